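#' Define a synthetic enhancer class
#'
#' A class recipe names the motifs implanted in each region of the class,
#' how many instances to place (fixed or Poisson-distributed counts), and
#' the positional window in which instances are placed uniformly at random
#' on a random strand.
#'
#' @param class_id Integer class identifier.
#' @param name Class name (used as topic/label name).
#' @param motifs A tibble with columns `motif` (name in the motif library),
#'   `count` (instances per region), and optionally `dist`
#'   (`"fixed"`, the default, or `"poisson"`), `window_start`,
#'   `window_end` (0-based region-local placement window). `NULL` means no
#'   motifs (pure background).
#' @param gc Background GC fraction in `[0, 1]`.
#' @param n_regions Number of regions to generate for the class.
#' @param region_length Region length in bp (default 500).
#' @return A `class_spec` list.
#' @export
class_spec <- function(class_id, name, motifs = NULL, gc = 0.41,
                       n_regions = 100L, region_length = 500L) {
  if (!is.null(motifs)) {
    motifs <- as_tibble(motifs)
    if (!"dist" %in% names(motifs)) motifs$dist <- "fixed"
    if (!"window_start" %in% names(motifs)) motifs$window_start <- 50L
    if (!"window_end" %in% names(motifs)) motifs$window_end <- region_length - 50L
    assert_that(all(motifs$count >= 0), "motif counts must be >= 0")
  }
  assert_that(gc >= 0 && gc <= 1, "`gc` must be in [0,1]")
  structure(
    list(class_id = as.integer(class_id), name = name, motifs = motifs,
         gc = gc, n_regions = as.integer(n_regions),
         region_length = as.integer(region_length)),
    class = "class_spec"
  )
}

#' Default four-class study design
#'
#' The bundled study conditions: a melanocytic-like class (SOX dimer,
#' E-box/MITF, TFAP2A and RUNX motifs), a mesenchymal-like class (AP-1 and
#' TEAD motifs), a GC-rich promoter-like class (SP-like motifs on a GC-rich
#' background), and a pure-background class.
#'
#' @param n_regions Regions per class.
#' @param region_length Region length in bp.
#' @return A list of four `class_spec` objects.
#' @export
default_class_specs <- function(n_regions = 3000L, region_length = 500L) {
  list(
    class_spec(1L, "MEL",
               motifs = tibble(motif = c("SOX_dimer", "MITF_ebox", "TFAP2A", "RUNX"),
                               count = c(2, 1, 1, 1)),
               n_regions = n_regions, region_length = region_length),
    class_spec(2L, "MES",
               motifs = tibble(motif = c("AP1", "TEAD"), count = c(2, 2)),
               n_regions = n_regions, region_length = region_length),
    class_spec(3L, "PROM",
               motifs = tibble(motif = "SP_GC", count = 3),
               gc = 0.55, n_regions = n_regions, region_length = region_length),
    class_spec(4L, "BG", motifs = NULL,
               n_regions = n_regions, region_length = region_length)
  )
}

sample_background <- function(n, gc) {
  sample.int(4L, n, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

sample_pwm_instance <- function(pwm) {
  vapply(seq_len(nrow(pwm)), function(k) {
    sample.int(4L, 1L, prob = pwm[k, ])
  }, integer(1))
}

#' Generate a synthetic cohort of class-labelled regions
#'
#' Regions are laid out on `n_chroms` synthetic chromosomes (round-robin
#' within each class, so every chromosome carries every class — supporting
#' chromosome-held-out splits) separated by background spacer sequence.
#' Motif instances are sampled from their PWMs, placed uniformly (without
#' overlap) in the recipe's positional window on a random strand, and
#' recorded as ground truth. Region scores carry the synthetic
#' accessibility signal computed by [activity_model()], clamped at 0.
#' Output is deterministic given `seed`.
#'
#' @param specs A `class_spec` or list of them.
#' @param seed Integer seed.
#' @param motifs Motif library tibble (default [motif_library()]).
#' @param n_chroms Number of synthetic chromosomes (default 10).
#' @param spacer Background bp between regions on a chromosome (default 200).
#' @return A `synthetic_cohort` list with elements `regions` (region tibble
#'   with `class` column; `score` = accessibility), `sequences` (named
#'   vector of region sequences), `genome` (chromosome sequences),
#'   `truth_hits` (tibble: region, motif, family, start, end, strand),
#'   `topic_probs` (N x T matrix), `label_matrix` (N x T binary),
#'   `classes`, `motifs`.
#' @export
simulate_regions <- function(specs, seed = 1L, motifs = motif_library(),
                             n_chroms = 10L, spacer = 200L) {
  if (inherits(specs, "class_spec")) specs <- list(specs)
  set.seed(seed)
  lib <- motifs
  all_regions <- list()
  all_seqs <- list()
  all_truth <- list()
  for (spec in specs) {
    L <- spec$region_length
    recipe <- spec$motifs
    if (!is.null(recipe)) {
      recipe_pwms <- lapply(recipe$motif, function(m) {
        i <- match(m, lib$name)
        assert_that(!is.na(i), paste0("motif not in library: ", m))
        lib$pwm[[i]]
      })
      widths <- vapply(recipe_pwms, nrow, integer(1))
      if (any(widths > L - 20L)) {
        abort(paste0("motif `", recipe$motif[which.max(widths)],
                     "` (width ", max(widths),
                     ") is too wide for region length ", L))
      }
    }
    for (i in seq_len(spec$n_regions)) {
      codes <- sample_background(L, spec$gc)
      hits <- list()
      occupied <- integer(0)
      if (!is.null(recipe)) {
        for (j in seq_len(nrow(recipe))) {
          n_inst <- if (identical(recipe$dist[j], "poisson")) {
            rpois(1L, recipe$count[j])
          } else {
            as.integer(recipe$count[j])
          }
          if (n_inst == 0L) next
          pwm <- recipe_pwms[[j]]
          W <- nrow(pwm)
          lo <- max(1L, recipe$window_start[j] + 1L)
          hi <- min(L - W + 1L, recipe$window_end[j] - W + 1L)
          for (k in seq_len(n_inst)) {
            placed <- FALSE
            for (try in 1:100) {
              s <- sample(lo:hi, 1L)
              span <- s:(s + W - 1L)
              if (!any(span %in% occupied)) {
                inst <- sample_pwm_instance(pwm)
                strand <- sample(c("+", "-"), 1L)
                if (strand == "-") inst <- rev(5L - inst)
                codes[span] <- inst
                occupied <- c(occupied, span)
                hits[[length(hits) + 1L]] <- tibble(
                  motif = recipe$motif[j], start = s - 1L, end = s + W - 1L,
                  strand = strand
                )
                placed <- TRUE
                break
              }
            }
            if (!placed) {
              warn(paste0("could not place `", recipe$motif[j],
                          "` without overlap; instance skipped"))
            }
          }
        }
      }
      rid <- sprintf("%s_%04d", tolower(spec$name), i)
      all_seqs[[rid]] <- decode_codes(codes)
      if (length(hits) > 0) {
        h <- dplyr::bind_rows(hits)
        h$region <- rid
        all_truth[[rid]] <- h
      }
      all_regions[[length(all_regions) + 1L]] <- tibble(
        name = rid, class = spec$name,
        chrom = paste0("chr", 1L + (i - 1L) %% n_chroms),
        length = L
      )
    }
  }
  regions <- dplyr::bind_rows(all_regions)
  # lay regions out per chromosome with background spacers
  genome <- character(0)
  starts <- integer(nrow(regions))
  for (chr in unique(regions$chrom)) {
    idx <- which(regions$chrom == chr)
    pieces <- character(2L * length(idx) + 1L)
    pos <- 0L
    pieces[1] <- decode_codes(sample_background(spacer, 0.45))
    pos <- spacer
    for (k in seq_along(idx)) {
      starts[idx[k]] <- pos
      pieces[2L * k] <- all_seqs[[regions$name[idx[k]]]]
      pos <- pos + regions$length[idx[k]]
      pieces[2L * k + 1L] <- decode_codes(sample_background(spacer, 0.45))
      pos <- pos + spacer
    }
    genome[chr] <- paste(pieces, collapse = "")
  }
  sequences <- unlist(all_seqs)[regions$name]
  truth <- if (length(all_truth) > 0) {
    th <- dplyr::bind_rows(all_truth)
    th$family <- lib$family[match(th$motif, lib$name)]
    th[, c("region", "motif", "family", "start", "end", "strand")]
  } else {
    tibble(region = character(), motif = character(), family = character(),
           start = integer(), end = integer(), strand = character())
  }
  accessibility <- vapply(sequences, function(s) {
    max(0, activity_from_codes(encode_sequence(s), lib))
  }, numeric(1), USE.NAMES = FALSE)
  classes <- vapply(specs, function(s) s$name, character(1))
  topic_probs <- matrix(runif(nrow(regions) * length(classes), 0, 0.9),
                        nrow(regions), length(classes),
                        dimnames = list(regions$name, classes))
  topic_probs[cbind(seq_len(nrow(regions)), match(regions$class, classes))] <- 1
  label_matrix <- matrix(0L, nrow(regions), length(classes),
                         dimnames = list(regions$name, classes))
  label_matrix[cbind(seq_len(nrow(regions)), match(regions$class, classes))] <- 1L
  region_tbl_out <- tibble(
    chrom = regions$chrom, start = starts,
    end = starts + regions$length, name = regions$name,
    score = accessibility, strand = ".", class = regions$class
  )
  structure(
    list(regions = region_tbl_out, sequences = sequences, genome = genome,
         truth_hits = truth, topic_probs = topic_probs,
         label_matrix = label_matrix, classes = classes, motifs = lib,
         seed = seed),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$regions), " regions, ",
      length(x$classes), " classes (", paste(x$classes, collapse = ", "),
      "), ", nrow(x$truth_hits), " implanted motif instances\n", sep = "")
  invisible(x)
}

#' Synthetic enhancer activity model
#'
#' A fixed, documented ground-truth activity: the weighted sum over motif
#' families of the family's best PWM log-odds match minus 75% of the
#' family's maximal possible score, with MITF-like weighted highest, then
#' SOX-like, then all others. Sequences with no motif content score at or
#' below 0; destroying an implanted instance strictly decreases activity.
#' Used as the oracle for mutagenesis-correlation tests and to derive
#' synthetic accessibility.
#'
#' @param sequence A DNA string.
#' @param motifs Motif library tibble.
#' @param weights Named family weights (default MITF = 2, SOX = 1.5,
#'   others = 1).
#' @return A single activity score (unbounded; 0-centred background).
#' @export
activity_model <- function(sequence, motifs = motif_library(),
                           weights = c(MITF = 2, SOX = 1.5)) {
  activity_from_codes(encode_sequence(sequence), motifs, weights)
}

activity_from_codes <- function(codes, motifs, weights = c(MITF = 2, SOX = 1.5)) {
  fams <- unique(motifs$family)
  total <- 0
  for (fam in fams) {
    idx <- which(motifs$family == fam)
    w <- if (fam %in% names(weights)) weights[[fam]] else 1
    fam_best <- -Inf
    fam_max <- -Inf
    for (i in idx) {
      pwm <- motifs$pwm[[i]]
      if (length(codes) >= nrow(pwm)) {
        fam_best <- max(fam_best,
                        scan_codes(codes, pwm),
                        scan_codes(codes, pwm_rc(pwm)))
      }
      lo <- pwm_log_odds(pwm)[, 1:4, drop = FALSE]
      fam_max <- max(fam_max, sum(apply(lo, 1, max)))
    }
    total <- total + w * (fam_best - 0.75 * fam_max)
  }
  total
}

#' Evolve a cohort along a phylogeny
#'
#' Applies Jukes-Cantor point substitutions along every branch of a rooted
#' tree (branch lengths in expected substitutions per site; a site changes
#' with probability `3/4 * (1 - exp(-4 t / 3))` and then picks one of the
#' other three bases uniformly). With `conserve_motifs = TRUE`, positions
#' inside implanted motif instances are exempt unless the instance is
#' selected for loss (probability `motif_loss_rate` per instance per
#' branch), in which case the whole instance is randomized and flagged
#' `intact = FALSE` in all descendant species. Indels (geometric lengths,
#' p = 0.5) are off by default and never placed inside motif instances;
#' truth hits are remapped through them.
#'
#' @param cohort A `synthetic_cohort`.
#' @param tree An `ape::phylo` tree (or Newick string/file) with branch
#'   lengths; leaves name the species.
#' @param conserve_motifs Protect implanted instances from substitutions.
#' @param motif_loss_rate Per-branch, per-instance probability of motif
#'   loss (whole-instance randomization).
#' @param indel_rate Per-site, per-branch indel event probability
#'   (default 0).
#' @param seed Integer seed.
#' @return An `evolved_cohort` list: `species`, `sequences` (list of named
#'   vectors per species), `truth_hits` (with `species` and `intact`
#'   columns), `tree`, `ancestor`.
#' @export
evolve_cohort <- function(cohort, tree, conserve_motifs = TRUE,
                          motif_loss_rate = 0, indel_rate = 0, seed = 1L) {
  assert_that(motif_loss_rate >= 0 && indel_rate >= 0,
              "rates must be nonnegative")
  tree <- as_phylo_tree(tree)
  assert_that(length(tree$tip.label) >= 2, "tree must have >= 2 leaves")
  assert_that(all(tree$edge.length >= 0), "branch lengths must be >= 0")
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  region_ids <- names(cohort$sequences)
  # per-node state: list of per-region code vectors + per-region hit tables
  anc_codes <- lapply(cohort$sequences, encode_sequence)
  anc_hits <- split(cohort$truth_hits, cohort$truth_hits$region)
  node_state <- list()
  node_state[[as.character(root)]] <- list(
    codes = anc_codes,
    hits = lapply(region_ids, function(r) {
      h <- anc_hits[[r]]
      if (is.null(h)) {
        h <- tibble(region = character(), motif = character(),
                    family = character(), start = integer(), end = integer(),
                    strand = character())
      }
      h$intact <- rep(TRUE, nrow(h))
      h
    })
  )
  names(node_state[[as.character(root)]]$hits) <- region_ids
  out_seqs <- list()
  out_hits <- list()
  # depth-first over edges in preorder
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  preorder <- order_edges_preorder(tree)
  for (e in preorder) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    t_len <- tree$edge.length[e]
    st <- node_state[[as.character(parent)]]
    new_codes <- st$codes
    new_hits <- st$hits
    for (r in region_ids) {
      res <- evolve_one(new_codes[[r]], new_hits[[r]], t_len,
                        conserve_motifs, motif_loss_rate, indel_rate)
      new_codes[[r]] <- res$codes
      new_hits[[r]] <- res$hits
    }
    if (child <= n_tip) {
      sp <- tree$tip.label[child]
      out_seqs[[sp]] <- vapply(new_codes, decode_codes, character(1))
      h <- dplyr::bind_rows(new_hits)
      if (nrow(h) > 0) h$species <- sp
      out_hits[[sp]] <- h
    } else {
      node_state[[as.character(child)]] <- list(codes = new_codes, hits = new_hits)
    }
  }
  truth <- dplyr::bind_rows(out_hits)
  structure(
    list(species = tree$tip.label, sequences = out_seqs, truth_hits = truth,
         tree = tree, ancestor = cohort, seed = seed),
    class = "evolved_cohort"
  )
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  abort("`tree` must be a phylo object, Newick string, or file path")
}

order_edges_preorder <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  out <- integer(0)
  stack <- root
  while (length(stack) > 0) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- which(tree$edge[, 1] == node)
    out <- c(out, kids)
    stack <- c(stack, tree$edge[kids, 2])
  }
  out
}

evolve_one <- function(codes, hits, t_len, conserve_motifs, motif_loss_rate,
                       indel_rate) {
  L <- length(codes)
  protected <- logical(L)
  if (conserve_motifs && nrow(hits) > 0) {
    for (j in which(hits$intact)) {
      protected[(hits$start[j] + 1L):hits$end[j]] <- TRUE
    }
  }
  # motif loss: randomize whole instance
  if (motif_loss_rate > 0 && nrow(hits) > 0) {
    for (j in seq_len(nrow(hits))) {
      if (hits$intact[j] && runif(1) < motif_loss_rate) {
        span <- (hits$start[j] + 1L):hits$end[j]
        codes[span] <- sample.int(4L, length(span), replace = TRUE)
        protected[span] <- FALSE
        hits$intact[j] <- FALSE
      }
    }
  }
  # Jukes-Cantor substitutions
  if (t_len > 0) {
    p_change <- 0.75 * (1 - exp(-4 * t_len / 3))
    mutable <- which(!protected & codes > 0L)
    flip <- mutable[runif(length(mutable)) < p_change]
    if (length(flip) > 0) {
      shift <- sample.int(3L, length(flip), replace = TRUE)
      codes[flip] <- 1L + (codes[flip] - 1L + shift) %% 4L
    }
  }
  # indels (never inside motif instances)
  if (indel_rate > 0) {
    n_events <- rbinom(1L, L, indel_rate)
    for (k in seq_len(n_events)) {
      L_now <- length(codes)
      in_motif <- logical(L_now)
      if (nrow(hits) > 0) {
        for (j in seq_len(nrow(hits))) {
          in_motif[(hits$start[j] + 1L):hits$end[j]] <- TRUE
        }
      }
      free <- which(!in_motif)
      if (length(free) == 0) break
      pos <- free[sample.int(length(free), 1L)]
      len <- stats::rgeom(1L, 0.5) + 1L
      if (runif(1) < 0.5) {
        # insertion after pos
        ins <- sample.int(4L, len, replace = TRUE)
        codes <- append(codes, ins, after = pos)
        if (nrow(hits) > 0) {
          move <- hits$start >= pos
          hits$start[move] <- hits$start[move] + len
          hits$end[move] <- hits$end[move] + len
        }
      } else {
        # deletion starting at pos, truncated at motif boundaries / seq end
        del_end <- pos
        while (del_end < L_now && del_end - pos + 1L < len &&
               !in_motif[del_end + 1L]) {
          del_end <- del_end + 1L
        }
        dlen <- del_end - pos + 1L
        codes <- codes[-(pos:del_end)]
        if (nrow(hits) > 0) {
          move <- hits$start >= del_end
          hits$start[move] <- hits$start[move] - dlen
          hits$end[move] <- hits$end[move] - dlen
        }
      }
    }
  }
  list(codes = codes, hits = hits)
}

#' Simulate ATAC-like fragments and a coverage track
#'
#' Samples `depth` fragments per region: the fragment midpoint is drawn
#' around the region centre (truncated normal) and fragment lengths
#' uniformly from `frag_len`. Every fragment overlaps its region. Also
#' returns the per-base coverage as a bedGraph-style track.
#'
#' @param regions A region tibble.
#' @param depth Fragments per region (must be >= 1).
#' @param frag_len Fragment length range (default `c(60, 150)`).
#' @param jitter_sd SD of the midpoint around the region centre (default 60).
#' @param seed Integer seed.
#' @return A list with `fragments` (tibble chrom/start/end/strand/region)
#'   and `coverage` (track tibble).
#' @export
simulate_fragments <- function(regions, depth, frag_len = c(60L, 150L),
                               jitter_sd = 60, seed = 1L) {
  assert_that(depth >= 1, "`depth` must be >= 1")
  regions <- as_region_tbl(regions)
  set.seed(seed)
  if (nrow(regions) == 0) {
    return(list(
      fragments = tibble(chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         region = character()),
      coverage = tibble(chrom = character(), start = integer(),
                        end = integer(), value = numeric())
    ))
  }
  frags <- lapply(seq_len(nrow(regions)), function(i) {
    centre <- summit_of(regions[i, ])
    mid <- round(rnorm(depth, centre, jitter_sd))
    mid <- pmin(pmax(mid, regions$start[i]), regions$end[i] - 1L)
    len <- sample(frag_len[1]:frag_len[2], depth, replace = TRUE)
    start <- pmax(0L, as.integer(mid - floor(len / 2)))
    tibble(chrom = regions$chrom[i], start = start,
           end = as.integer(start + len),
           strand = sample(c("+", "-"), depth, replace = TRUE),
           region = regions$name[i])
  })
  frags <- dplyr::bind_rows(frags)
  coverage <- coverage_track(frags)
  list(fragments = frags, coverage = coverage)
}

# Per-base coverage of intervals as a bedGraph tibble (zero runs omitted).
coverage_track <- function(intervals) {
  out <- lapply(split(intervals, intervals$chrom), function(df) {
    span <- max(df$end)
    cov <- numeric(span)
    for (i in seq_len(nrow(df))) {
      idx <- (df$start[i] + 1L):df$end[i]
      cov[idx] <- cov[idx] + 1
    }
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    tibble(chrom = df$chrom[1], start = as.integer(starts[keep]),
           end = as.integer(ends[keep]), value = r$values[keep])
  })
  dplyr::bind_rows(out)
}

#' Write a cohort to disk in standard formats
#'
#' Writes regions as BED6, sequences as FASTA, implanted motif instances
#' as BED6 (name = motif, score = 1000), the topic probability matrix as
#' TSV, and accessibility as bedGraph. For evolved cohorts, per-species
#' FASTA/BED files and the tree (Newick) are written.
#'
#' @param cohort A `synthetic_cohort` or `evolved_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (inherits(cohort, "evolved_cohort")) {
    for (sp in cohort$species) {
      f <- file.path(dir, paste0(sp, ".fa"))
      write_fasta(cohort$sequences[[sp]], f)
      files <- c(files, f)
      th <- cohort$truth_hits[cohort$truth_hits$species == sp, , drop = FALSE]
      if (nrow(th) > 0) {
        b <- file.path(dir, paste0(sp, "_truth.bed"))
        write_bed(tibble(chrom = th$region, start = th$start, end = th$end,
                         name = th$motif, score = 1000, strand = th$strand), b)
        files <- c(files, b)
      }
    }
    f <- file.path(dir, "tree.nwk")
    ape::write.tree(cohort$tree, f)
    files <- c(files, f)
    return(invisible(files))
  }
  f_bed <- file.path(dir, "regions.bed")
  write_bed(cohort$regions, f_bed)
  f_fa <- file.path(dir, "sequences.fa")
  write_fasta(cohort$sequences, f_fa)
  th <- cohort$truth_hits
  f_truth <- file.path(dir, "truth_hits.bed")
  write_bed(tibble(chrom = th$region, start = th$start, end = th$end,
                   name = th$motif, score = 1000, strand = th$strand), f_truth)
  f_topics <- file.path(dir, "topic_probs.tsv")
  readr::write_tsv(
    dplyr::bind_cols(tibble(region = rownames(cohort$topic_probs)),
                     as_tibble(cohort$topic_probs)),
    f_topics, progress = FALSE
  )
  f_acc <- file.path(dir, "accessibility.bedgraph")
  write_bedgraph(tibble(chrom = cohort$regions$chrom,
                        start = cohort$regions$start,
                        end = cohort$regions$end,
                        value = cohort$regions$score), f_acc)
  invisible(c(files, f_bed, f_fa, f_truth, f_topics, f_acc))
}
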