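#' Count passing motif hits per region and family
#'
#' @param hits A hit tibble (from [scan_motif_instances()], ideally after
#'   [dedupe_hits()]); only rows with `passes_threshold` are counted. Hits
#'   with no family are counted under `"other"` (with a warning).
#' @param regions Region universe: character vector of region names (or a
#'   region tibble); regions without hits get zero rows.
#' @param families Fixed family column set (default: families observed).
#' @return A tibble: `region` plus one integer count column per family.
#' @export
count_motif_hits <- function(hits, regions = NULL, families = NULL) {
  if (is.data.frame(regions)) regions <- regions$name
  hits <- hits[hits$passes_threshold %||% TRUE, , drop = FALSE]
  if (any(is.na(hits$family))) {
    warn("hits without a family assignment counted under 'other'")
    hits$family[is.na(hits$family)] <- "other"
  }
  families <- families %||% sort(unique(hits$family))
  regions <- regions %||% sort(unique(hits$region))
  counts <- matrix(0L, length(regions), length(families),
                   dimnames = list(regions, families))
  if (nrow(hits) > 0) {
    keep <- hits$region %in% regions & hits$family %in% families
    tb <- table(factor(hits$region[keep], levels = regions),
                factor(hits$family[keep], levels = families))
    counts[] <- as.integer(tb)
  }
  dplyr::bind_cols(tibble(region = regions), as_tibble(as.data.frame.matrix(counts)))
}

#' Binarize motif counts and cluster regions by composition
#'
#' Presence is `count >= 1`; each region's composition class is the set of
#' families present (label: families joined by `+`, `"none"` when empty).
#' Classes are exactly the distinct composition vectors observed. If
#' `require_family` is given, regions lacking that family are reported in
#' a separate non-conforming bucket rather than dropped.
#'
#' @param counts A count tibble from [count_motif_hits()].
#' @param require_family Optional family that conforming regions must
#'   contain (e.g. the SOX dimer in melanocytic enhancers).
#' @return A `composition_classes` list: `assignments` (tibble `region`,
#'   `class`, `conforming`) and `inventory` (tibble `class`, `n`,
#'   `conforming`).
#' @export
classify_composition <- function(counts, require_family = NULL) {
  fams <- setdiff(names(counts), "region")
  pres <- as.matrix(counts[, fams, drop = FALSE]) >= 1
  label <- apply(pres, 1, function(row) {
    if (!any(row)) "none" else paste(fams[row], collapse = "+")
  })
  conforming <- if (is.null(require_family)) {
    rep(TRUE, nrow(counts))
  } else {
    assert_that(require_family %in% fams,
                paste0("family not in counts: ", require_family))
    pres[, require_family]
  }
  assignments <- tibble(region = counts$region, class = label,
                        conforming = conforming)
  inventory <- assignments %>%
    dplyr::count(.data$class, .data$conforming, name = "n") %>%
    dplyr::arrange(dplyr::desc(.data$n))
  structure(list(assignments = assignments, inventory = inventory),
            class = "composition_classes")
}

#' @export
print.composition_classes <- function(x, ...) {
  n_cls <- length(unique(x$assignments$class[x$assignments$conforming]))
  cat("<composition_classes> ", nrow(x$assignments), " regions, ", n_cls,
      " conforming composition classes, ",
      sum(!x$assignments$conforming), " non-conforming\n", sep = "")
  print(x$inventory)
  invisible(x)
}

# Normalize anchors to tibble(chrom, center, strand).
normalize_anchors <- function(anchors) {
  if (all(c("chrom", "start", "end") %in% names(anchors))) {
    tibble(chrom = anchors$chrom,
           center = summit_of(anchors),
           strand = anchors$strand %||% ".")
  } else if (all(c("region", "center") %in% names(anchors))) {
    tibble(chrom = anchors$region,
           center = as.integer(round(anchors$center)),
           strand = anchors$strand %||% ".")
  } else {
    abort("anchors must be a region tibble or a motif-hit tibble")
  }
}

# Dense per-chrom signal vectors from a bedGraph tibble.
track_vectors <- function(track) {
  lapply(split(track, track$chrom), function(df) {
    v <- numeric(max(df$end))
    for (i in seq_len(nrow(df))) {
      v[(df$start[i] + 1L):df$end[i]] <- df$value[i]
    }
    v
  })
}

#' Aggregate a signal track around anchors
#'
#' Averages per-base signal over identical-length windows centred on each
#' anchor (region summit or motif-hit centre). Motif-anchored windows are
#' oriented by the hit strand (minus-strand windows are flipped) so that
#' asymmetric positional preferences are preserved. Anchors whose flanks
#' leave the track are excluded and counted.
#'
#' @param track A bedGraph-style track tibble (`chrom`, `start`, `end`,
#'   `value`); for region-local tracks the `chrom` field holds region
#'   names.
#' @param anchors Region tibble (summit anchoring) or hit tibble (motif
#'   anchoring).
#' @param flank_bp Half-window size; offsets run from `-flank_bp` to
#'   `+flank_bp`.
#' @return An `aggregate_profile` tibble: `offset`, `mean`, `n`;
#'   `attr(, "excluded")` counts out-of-range anchors.
#' @export
aggregate_signal <- function(track, anchors, flank_bp = 250L) {
  anc <- normalize_anchors(anchors)
  tv <- track_vectors(track)
  width <- 2L * flank_bp + 1L
  acc <- numeric(width)
  n <- 0L
  excluded <- 0L
  for (i in seq_len(nrow(anc))) {
    v <- tv[[anc$chrom[i]]]
    if (is.null(v)) { excluded <- excluded + 1L; next }
    lo <- anc$center[i] - flank_bp + 1L
    hi <- anc$center[i] + flank_bp + 1L
    if (lo < 1L || hi > length(v)) { excluded <- excluded + 1L; next }
    w <- v[lo:hi]
    if (identical(anc$strand[i], "-")) w <- rev(w)
    acc <- acc + w
    n <- n + 1L
  }
  out <- tibble(offset = seq(-flank_bp, flank_bp),
                mean = if (n > 0) acc / n else acc * NA_real_,
                n = n)
  attr(out, "excluded") <- excluded
  class(out) <- c("aggregate_profile", class(out))
  out
}

#' Tn5 cut-site profile around anchors
#'
#' Infers Tn5 cut sites from fragment ends (the 5' start of each read:
#' both the fragment start and its final base) and aggregates per-offset
#' cut counts over all anchors. The +4/-5 Tn5 offset correction is off by
#' default (raw read starts), available via `offset_correct`.
#'
#' @param fragments Fragment tibble (`chrom`, `start`, `end`; 0-based
#'   half-open).
#' @param anchors Region or hit tibble (see [aggregate_signal()]).
#' @param flank_bp Half-window size.
#' @param offset_correct Apply the +4/-5 transposase offset.
#' @return An `aggregate_profile` tibble: `offset`, `count`, `n` (anchors
#'   used).
#' @export
tn5_cut_profile <- function(fragments, anchors, flank_bp = 250L,
                            offset_correct = FALSE) {
  anc <- normalize_anchors(anchors)
  shift5 <- if (offset_correct) 4L else 0L
  shift3 <- if (offset_correct) -5L else 0L
  cuts <- tibble(
    chrom = rep(fragments$chrom, 2L),
    pos = c(fragments$start + shift5, fragments$end - 1L + shift3)
  )
  cuts_by_chrom <- split(cuts$pos, cuts$chrom)
  width <- 2L * flank_bp + 1L
  acc <- numeric(width)
  n <- 0L
  for (i in seq_len(nrow(anc))) {
    p <- cuts_by_chrom[[anc$chrom[i]]]
    if (is.null(p)) { n <- n + 1L; next }
    offs <- p - anc$center[i]
    offs <- offs[offs >= -flank_bp & offs <= flank_bp]
    if (identical(anc$strand[i], "-")) offs <- -offs
    if (length(offs) > 0) {
      acc <- acc + tabulate(offs + flank_bp + 1L, nbins = width)
    }
    n <- n + 1L
  }
  out <- tibble(offset = seq(-flank_bp, flank_bp), count = acc, n = n)
  class(out) <- c("aggregate_profile", class(out))
  out
}
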