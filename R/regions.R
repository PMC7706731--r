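#' Build a region tibble
#'
#' Regions are plain tibbles in BED convention: 0-based, half-open
#' `[start, end)` coordinates, with columns `chrom`, `start`, `end`,
#' `name`, `score`, `strand`. All region-handling functions in the package
#' take and return this shape.
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive starts.
#' @param end 0-based exclusive ends (`end > start`).
#' @param name Region identifiers (defaults to `region_<i>`).
#' @param score Numeric scores (default 0).
#' @param strand One of `"+"`, `"-"`, `"."` (default `"."`).
#' @return A tibble with the six BED columns.
#' @export
region_tbl <- function(chrom, start, end, name = NULL, score = 0, strand = ".") {
  n <- length(chrom)
  name <- name %||% paste0("region_", seq_len(n))
  out <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand)
  )
  validate_regions(out)
  out
}

validate_regions <- function(regions, context = "regions") {
  assert_that(is.data.frame(regions) &&
                all(c("chrom", "start", "end") %in% names(regions)),
              paste0(context, " must have chrom/start/end columns"))
  bad <- which(regions$end <= regions$start | regions$start < 0)
  if (length(bad) > 0) {
    abort(paste0(context, ": invalid interval at row ", bad[1],
                 " (need 0 <= start < end)"))
  }
  if ("score" %in% names(regions) && anyNA(regions$score)) {
    abort(paste0(context, ": NaN/NA scores are not allowed"))
  }
  invisible(regions)
}

as_region_tbl <- function(df) {
  df <- as_tibble(df)
  if (!"name" %in% names(df)) df$name <- paste0("region_", seq_len(nrow(df)))
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "."
  validate_regions(df)
  df[, c("chrom", "start", "end", "name", "score", "strand")]
}

#' Read / write BED files
#'
#' `read_bed()` accepts BED3 to BED6; missing columns are filled with
#' defaults. Malformed lines (non-numeric coordinates or `end <= start`)
#' raise an error naming the offending line. `write_bed()` writes BED6.
#'
#' @param path File path.
#' @return `read_bed()` returns a region tibble.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) return(region_tbl(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields"))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0)
  if (length(bad) > 0) {
    abort(paste0("malformed BED line ", bad[1], ": invalid interval"))
  }
  tibble(
    chrom = vapply(fields, `[`, "", 1L),
    start = start,
    end = end,
    name = ifelse(nf >= 4, vapply(fields, function(f) f[4], ""), paste0("region_", seq_along(fields))),
    score = ifelse(nf >= 5, suppressWarnings(as.numeric(vapply(fields, function(f) if (length(f) >= 5) f[5] else "0", ""))), 0),
    strand = ifelse(nf >= 6, vapply(fields, function(f) if (length(f) >= 6) f[6] else ".", ""), ".")
  )
}

#' @param regions A region tibble.
#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  regions <- as_region_tbl(regions)
  writeLines(
    paste(regions$chrom, regions$start, regions$end, regions$name,
          regions$score, regions$strand, sep = "\t"),
    path
  )
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings returning plain named character vectors.
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @param sequences Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- names(sequences) %||% paste0("seq_", seq_along(sequences))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write bedGraph signal tracks
#'
#' Tracks are tibbles with columns `chrom`, `start`, `end`, `value`
#' (0-based, half-open intervals with constant signal).
#'
#' @param path File path.
#' @return `read_bedgraph()` returns a track tibble.
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                  col_types = "ciid", progress = FALSE)
}

#' @param track A track tibble.
#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

summit_of <- function(regions) {
  as.integer(floor((regions$start + regions$end) / 2))
}

#' Augment regions by extending and sliding a window
#'
#' Each region is extended to `extended_width` bp around its summit
#' (`floor((start + end) / 2)`), and a `window`-bp window slides over the
#' extension with a `stride`-bp step, producing
#' `floor((extended_width - window) / stride) + 1` windows per parent.
#' With the defaults (700/500/10) every region yields 21 windows. The
#' parent identifier is retained in the window name
#' (`<parent>_win<k>`) and in a `parent` column.
#'
#' @param regions A region tibble.
#' @param extended_width Width of the extension around the summit (bp).
#' @param window Window width (bp).
#' @param stride Step between consecutive windows (bp).
#' @return A region tibble of windows with a `parent` column.
#' @export
extend_and_slide <- function(regions, extended_width = 700L, window = 500L,
                             stride = 10L) {
  assert_that(window <= extended_width, "`window` must be <= `extended_width`")
  assert_that(stride >= 1, "`stride` must be >= 1")
  regions <- as_region_tbl(regions)
  n_win <- floor((extended_width - window) / stride) + 1L
  summit <- summit_of(regions)
  ext_start <- pmax(0L, summit - floor(extended_width / 2))
  offsets <- (seq_len(n_win) - 1L) * stride
  out <- tidyr::crossing(
    tibble(chrom = regions$chrom, ext_start = ext_start,
           parent = regions$name, score = regions$score,
           strand = regions$strand),
    tibble(offset = offsets, k = seq_len(n_win))
  )
  tibble(
    chrom = out$chrom,
    start = as.integer(out$ext_start + out$offset),
    end = as.integer(out$ext_start + out$offset + window),
    name = paste0(out$parent, "_win", out$k),
    score = out$score,
    strand = out$strand,
    parent = out$parent
  )
}

# Maximum overlap (bp) of each query region with any subject region.
max_overlap_bp <- function(query, subject) {
  out <- numeric(nrow(query))
  if (nrow(subject) == 0 || nrow(query) == 0) return(out)
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- which(subject$chrom == chr)
    if (length(si) == 0) next
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    hits <- IRanges::findOverlaps(qr, sr)
    if (length(hits) == 0) next
    ow <- IRanges::width(IRanges::pintersect(
      qr[S4Vectors::queryHits(hits)], sr[S4Vectors::subjectHits(hits)]
    ))
    agg <- tapply(ow, S4Vectors::queryHits(hits), max)
    out[qi[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}

#' Label windows by overlap with topic region sets
#'
#' A window is labelled with a topic when it overlaps some region of that
#' topic by at least `min_overlap_frac` of the window's own length
#' (inclusive `>=`, matching `bedtools intersect -f` semantics). Windows
#' may receive multiple labels (multilabel) or none.
#'
#' @param windows A region tibble of candidate training windows.
#' @param topic_regions A named list of region tibbles, one per topic.
#' @param min_overlap_frac Minimum overlap fraction of the window (default 0.6).
#' @return A binary N x T label matrix with topic names as columns and
#'   window names as rows.
#' @export
assign_labels <- function(windows, topic_regions, min_overlap_frac = 0.6) {
  windows <- as_region_tbl(windows)
  lab <- matrix(0L, nrow(windows), length(topic_regions),
                dimnames = list(windows$name, names(topic_regions)))
  w_len <- windows$end - windows$start
  for (t in seq_along(topic_regions)) {
    ov <- max_overlap_bp(windows, as_region_tbl(topic_regions[[t]]))
    lab[, t] <- as.integer(ov >= min_overlap_frac * w_len)
  }
  lab
}

#' Binarize a topic probability matrix
#'
#' Assigns a region to a topic when its topic probability is greater than
#' or equal to `threshold` (inclusive; default 0.995).
#'
#' @param probs N x T numeric matrix of topic probabilities with region
#'   names as rownames.
#' @param regions A region tibble whose `name` column matches
#'   `rownames(probs)`.
#' @param threshold Probability cutoff in (0, 1).
#' @return A named list of region tibbles, one per topic.
#' @export
binarize_topics <- function(probs, regions, threshold = 0.995) {
  assert_that(threshold > 0 && threshold < 1, "`threshold` must be in (0,1)")
  regions <- as_region_tbl(regions)
  assert_that(!is.null(rownames(probs)), "`probs` needs region rownames")
  topics <- colnames(probs) %||% paste0("topic_", seq_len(ncol(probs)))
  out <- lapply(seq_len(ncol(probs)), function(t) {
    members <- rownames(probs)[probs[, t] >= threshold]
    regions[regions$name %in% members, , drop = FALSE]
  })
  setNames(out, topics)
}

#' Bootstrap pseudo-cell fragment subsets
#'
#' Emulates the construction of simulated single cells from bulk fragment
#' data: each pseudo-cell receives `reads_per_cell` fragments sampled with
#' replacement from the input.
#'
#' @param fragments A fragment tibble (chrom/start/end/strand).
#' @param n_cells Number of pseudo-cells (default 50).
#' @param reads_per_cell Fragments per pseudo-cell (default 50000).
#' @param seed Integer seed.
#' @return A list of `n_cells` fragment tibbles.
#' @export
bootstrap_pseudocells <- function(fragments, n_cells = 50L,
                                  reads_per_cell = 50000L, seed = 1L) {
  assert_that(nrow(fragments) > 0, "`fragments` must be nonempty")
  set.seed(seed)
  lapply(seq_len(n_cells), function(i) {
    fragments[sample.int(nrow(fragments), reads_per_cell, replace = TRUE), ,
              drop = FALSE]
  })
}

#' Tile a genome with fixed windows
#'
#' Produces windows starting at 0, `shift`, `2 * shift`, ... with
#' `end <= chromosome length`; windows containing any ambiguous base (`N`)
#' are removed, as is done before genome-wide scoring.
#'
#' @param genome Named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a FASTA path.
#' @param chroms Optional subset of chromosome names; an unknown name is an
#'   error.
#' @param window Window width (default 500).
#' @param shift Step between window starts (default 100).
#' @return A region tibble of surviving tiles.
#' @export
tile_genome <- function(genome, chroms = NULL, window = 500L, shift = 100L) {
  assert_that(window >= 1, "`window` must be >= 1")
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  chroms <- chroms %||% names(genome)
  missing <- setdiff(chroms, names(genome))
  if (length(missing) > 0) {
    abort(paste0("chromosome(s) not in genome: ", paste(missing, collapse = ", ")))
  }
  out <- lapply(chroms, function(chr) {
    L <- nchar(genome[[chr]])
    if (L < window) return(NULL)
    starts <- seq(0L, L - window, by = shift)
    has_n <- vapply(starts, function(s) {
      grepl("N", substr(genome[[chr]], s + 1L, s + window), fixed = TRUE)
    }, logical(1))
    starts <- starts[!has_n]
    if (length(starts) == 0) return(NULL)
    tibble(chrom = chr, start = as.integer(starts),
           end = as.integer(starts + window),
           name = paste0(chr, ":", starts, "-", starts + window),
           score = 0, strand = ".")
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(region_tbl(character(), integer(), integer()))
  }
  out
}

#' Conserved accessible regions
#'
#' Keeps mapped regions whose overlap with any target peak covers at least
#' `min_frac` of the mapped region's length (inclusive `>=`, matching
#' `bedtools intersect -f 0.6`).
#'
#' @param mapped_regions Region tibble in the target coordinate system.
#' @param target_peaks Region tibble of accessible peaks.
#' @param min_frac Minimum overlap fraction (default 0.6).
#' @return The subset of `mapped_regions` that is conserved accessible.
#' @export
conserved_accessible <- function(mapped_regions, target_peaks, min_frac = 0.6) {
  mapped_regions <- as_region_tbl(mapped_regions)
  if (nrow(mapped_regions) == 0) return(mapped_regions)
  if (nrow(target_peaks) == 0) return(mapped_regions[0, , drop = FALSE])
  ov <- max_overlap_bp(mapped_regions, as_region_tbl(target_peaks))
  keep <- ov >= min_frac * (mapped_regions$end - mapped_regions$start)
  mapped_regions[keep, , drop = FALSE]
}

#' Extract region sequences from a genome
#'
#' @param regions A region tibble.
#' @param genome Named character vector of chromosome sequences (or FASTA
#'   path).
#' @return A named character vector of region sequences (names = region
#'   names); minus-strand regions are reverse complemented.
#' @export
region_sequences <- function(regions, genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  regions <- as_region_tbl(regions)
  missing <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing) > 0) {
    abort(paste0("chromosome(s) not in genome: ", paste(missing, collapse = ", ")))
  }
  seqs <- vapply(seq_len(nrow(regions)), function(i) {
    s <- substr(genome[[regions$chrom[i]]], regions$start[i] + 1L, regions$end[i])
    if (identical(regions$strand[i], "-")) s <- reverse_complement(s)
    s
  }, character(1))
  setNames(seqs, regions$name)
}
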