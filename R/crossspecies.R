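#' Simplified cis-regulatory module (CRM) score
#'
#' Scores a sequence for one motif as the maximum, over all `window_bp`
#' windows, of the best non-overlapping placement sum of positive
#' best-strand PWM log-odds hits (log-odds above `hit_floor`; uniform 0.25
#' background). This is a documented simplification of HMM-based CRM
#' scorers: only relative scores are consumed downstream (by branch
#' length scoring), for which the optimal-placement sum is sufficient.
#'
#' @param sequence A DNA string.
#' @param motif A one-row motif tibble or PWM matrix.
#' @param window_bp Window size (default 500; windows slide at 1-bp
#'   resolution).
#' @param hit_floor Minimum per-hit log-odds (default 0; strictly greater
#'   scores count).
#' @return A nonnegative score (0 when no position exceeds the floor).
#' @export
crm_score <- function(sequence, motif, window_bp = 500L, hit_floor = 0) {
  pwm <- extract_pwm(motif)
  W <- nrow(pwm)
  assert_that(window_bp >= W, "`window_bp` must be >= motif width")
  codes <- encode_sequence(sequence)
  L <- length(codes)
  if (L < W) return(0)
  s <- pmax(scan_codes(codes, pwm), scan_codes(codes, pwm_rc(pwm)))
  s[s <= hit_floor] <- -Inf
  n_pos <- length(s)
  if (all(!is.finite(s))) return(0)
  if (L <= window_bp) {
    return(best_placement_sum(s, W))
  }
  best <- 0
  for (a in seq_len(L - window_bp + 1L)) {
    b <- a + window_bp - W
    best <- max(best, best_placement_sum(s[a:b], W))
  }
  best
}

# Optimal non-overlapping placement sum by weighted-interval DP.
best_placement_sum <- function(s, W) {
  n <- length(s)
  dp <- numeric(n + 1L)
  for (i in seq_len(n)) {
    # dp[j + 1] = best score using positions 1..j; a hit at i blocks i-W+1..i-1
    take <- if (is.finite(s[i])) s[i] + dp[max(i - W, 0L) + 1L] else -Inf
    dp[i + 1L] <- max(dp[i], take)
  }
  dp[n + 1L]
}

#' Branch length score (BLS) of a motif across species
#'
#' A species is motif-positive when its CRM score exceeds
#' `presence_threshold` (strictly; default 0). The BLS is the total branch
#' length of the minimal subtree of the phylogeny connecting the positive
#' leaves (0 when at most one leaf is positive; the full tree length when
#' all are).
#'
#' @param tree An `ape::phylo` tree (or Newick string/file).
#' @param species_scores Named numeric vector of per-species CRM scores;
#'   all names must be tree leaves.
#' @param presence_threshold Presence cutoff (default 0, strict `>`).
#' @param weight_by_score If `TRUE`, each subtree edge is weighted by the
#'   ratio of the smaller flanking positive score maximum to the overall
#'   maximum (exploratory score-weighted variant; default `FALSE`).
#' @return The branch length score.
#' @export
bls <- function(tree, species_scores, presence_threshold = 0,
                weight_by_score = FALSE) {
  tree <- as_phylo_tree(tree)
  missing <- setdiff(names(species_scores), tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("species not in tree: ", paste(missing, collapse = ", ")))
  }
  pos <- names(species_scores)[species_scores > presence_threshold]
  if (length(pos) <= 1L) return(0)
  below <- tips_below(tree)
  n_pos_total <- length(pos)
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips_e <- below[[tree$edge[e, 2]]]
    n_below <- sum(tips_e %in% pos)
    if (n_below > 0 && n_below < n_pos_total) {
      w <- 1
      if (weight_by_score) {
        s_below <- max(species_scores[intersect(tips_e, pos)])
        s_above <- max(species_scores[setdiff(pos, tips_e)])
        w <- min(s_below, s_above) / max(species_scores[pos])
      }
      total <- total + tree$edge.length[e] * w
    }
  }
  total
}

# Tip labels below each node (index = node id).
tips_below <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  below <- vector("list", n_node)
  for (i in seq_len(n_tip)) below[[i]] <- tree$tip.label[i]
  # postorder: children before parents
  for (e in rev(seq_len(nrow(tree$edge)))) {
    # ape's default edge ordering is cladewise; build bottom-up iteratively
  }
  repeat {
    changed <- FALSE
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]
      ch <- tree$edge[e, 2]
      if (!is.null(below[[ch]])) {
        add <- setdiff(below[[ch]], below[[par]])
        if (length(add) > 0) {
          below[[par]] <- c(below[[par]], add)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  below
}

#' Mononucleotide shuffle of a sequence
#'
#' Random permutation of the bases; preserves length and base composition
#' exactly.
#'
#' @param sequence A DNA string.
#' @param seed Optional integer seed.
#' @return The shuffled string.
#' @export
shuffle_sequence <- function(sequence, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codes <- encode_sequence(sequence)
  decode_codes(codes[sample.int(length(codes))])
}

#' Motif conservation table by branch length scoring
#'
#' For every motif: per-region, per-species CRM scores give a region BLS;
#' the sum over regions is the motif's true summed BLS. The same
#' computation on composition-preserving shuffles of every sequence gives
#' the shuffled BLS, and the normalized BLS is their difference. Motifs
#' are ranked by normalized BLS.
#'
#' @param sequences Named list: species -> named character vector of
#'   region sequences (same region names per species), e.g.
#'   `evolved_cohort$sequences`.
#' @param motifs Motif library tibble.
#' @param tree Phylogeny covering the species.
#' @param presence_threshold Passed to [bls()].
#' @param window_bp Passed to [crm_score()].
#' @param shuffler Shuffle function `(sequence, seed) -> sequence` (test
#'   hook; default [shuffle_sequence()]).
#' @param seed Integer seed for the shuffles.
#' @return A `bls_table` tibble: `motif`, `family`, `true_bls`,
#'   `shuffled_bls`, `normalized_bls`, `rank`; region-level scores in
#'   `attr(, "regions")`.
#' @export
bls_table <- function(sequences, motifs, tree, presence_threshold = 0,
                      window_bp = 500L, shuffler = shuffle_sequence,
                      seed = 1L) {
  tree <- as_phylo_tree(tree)
  species <- names(sequences)
  assert_that(length(species) >= 2, "need >= 2 species")
  region_ids <- names(sequences[[1]])
  set.seed(seed)
  shuffled <- lapply(sequences, function(sp_seqs) {
    vapply(seq_along(sp_seqs), function(i) {
      shuffler(sp_seqs[[i]], seed = sample.int(2^30, 1))
    }, character(1)) |> setNames(names(sp_seqs))
  })
  region_rows <- list()
  out <- lapply(seq_len(nrow(motifs)), function(m) {
    true_vals <- numeric(length(region_ids))
    shuf_vals <- numeric(length(region_ids))
    for (ri in seq_along(region_ids)) {
      r <- region_ids[ri]
      sc_true <- vapply(species, function(sp) {
        crm_score(sequences[[sp]][[r]], motifs$pwm[[m]], window_bp = window_bp)
      }, numeric(1))
      sc_shuf <- vapply(species, function(sp) {
        crm_score(shuffled[[sp]][[r]], motifs$pwm[[m]], window_bp = window_bp)
      }, numeric(1))
      true_vals[ri] <- bls(tree, sc_true, presence_threshold)
      shuf_vals[ri] <- bls(tree, sc_shuf, presence_threshold)
    }
    region_rows[[motifs$name[m]]] <<- tibble(
      motif = motifs$name[m], region = region_ids,
      true_bls = true_vals, shuffled_bls = shuf_vals
    )
    tibble(motif = motifs$name[m], family = motifs$family[m],
           true_bls = sum(true_vals), shuffled_bls = sum(shuf_vals),
           normalized_bls = sum(true_vals) - sum(shuf_vals))
  })
  out <- dplyr::bind_rows(out)
  out$rank <- rank(-out$normalized_bls, ties.method = "first")
  out <- out[order(out$rank), ]
  attr(out, "regions") <- dplyr::bind_rows(region_rows)
  class(out) <- c("bls_table", class(out))
  out
}

#' Affine-gap global alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`) and EDNAFULL-style
#' match/mismatch scores, computed by `Biostrings::pairwiseAlignment`.
#' Identity is matches divided by alignment length, in percent.
#'
#' @param a,b DNA strings (nonempty).
#' @param gap_open,gap_extend Affine gap parameters (defaults 10.0 / 0.5).
#' @param match,mismatch Substitution scores (defaults 5 / -4).
#' @return An `alignment_result`: `aligned_a`, `aligned_b`, `score`,
#'   `identity` (percent), `substitutions` (tibble `pos_a` 0-based, `ref`,
#'   `alt`), `indels` (tibble `type`, `pos_a`, `length`).
#' @export
global_align <- function(a, b, gap_open = 10.0, gap_extend = 0.5,
                         match = 5, mismatch = -4) {
  assert_that(nchar(a) > 0 && nchar(b) > 0, "sequences must be nonempty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  sa <- as.character(Biostrings::alignedPattern(aln))
  sb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  n <- length(ca)
  matches <- sum(ca == cb & ca != "-")
  pos_a <- cumsum(ca != "-")   # 1-based position in a at each column
  subs <- which(ca != "-" & cb != "-" & ca != cb)
  substitutions <- tibble(pos_a = pos_a[subs] - 1L, ref = ca[subs],
                          alt = cb[subs])
  gap_runs <- function(isgap, kind) {
    r <- rle(isgap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    tibble(type = rep(kind, length(keep)),
           pos_a = vapply(starts[keep], function(s) {
             as.integer(max(pos_a[s] - ifelse(kind == "insertion", 0L, 1L), 0L))
           }, integer(1)),
           length = r$lengths[keep])
  }
  indels <- dplyr::bind_rows(
    gap_runs(ca == "-", "insertion"),   # gap in a: extra bases in b
    gap_runs(cb == "-", "deletion")     # gap in b: bases of a missing in b
  )
  structure(
    list(aligned_a = sa, aligned_b = sb, score = as.numeric(Biostrings::score(aln)),
         identity = 100 * matches / n, substitutions = substitutions,
         indels = indels, n_columns = n),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> score ", round(x$score, 2), ", identity ",
      round(x$identity, 2), "%, ", nrow(x$substitutions),
      " substitutions, ", nrow(x$indels), " indels\n", sep = "")
  invisible(x)
}

# Exhaustive alignment-score oracle (all monotone alignments) for short
# sequences; same gap convention as global_align. Used in tests.
align_score_bruteforce <- function(a, b, gap_open = 10.0, gap_extend = 0.5,
                                   match = 5, mismatch = -4) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  recurse <- function(i, j, state) {
    # state: 0 none, 1 in gap of a (insertion), 2 in gap of b (deletion)
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      best <- max(best, s + recurse(i + 1, j + 1, 0))
    }
    if (j <= length(cb)) {  # gap in a
      pen <- gap_extend + if (state == 1) 0 else gap_open
      best <- max(best, recurse(i, j + 1, 1) - pen)
    }
    if (i <= length(ca)) {  # gap in b
      pen <- gap_extend + if (state == 2) 0 else gap_open
      best <- max(best, recurse(i + 1, j, 2) - pen)
    }
    best
  }
  recurse(1, 1, 0)
}

# Center a sequence in a fixed window: trim symmetrically or pad with N.
pad_or_trim <- function(sequence, L) {
  n <- nchar(sequence)
  if (n == L) return(sequence)
  if (n > L) {
    off <- floor((n - L) / 2)
    return(substr(sequence, off + 1L, off + L))
  }
  left <- floor((L - n) / 2)
  paste0(strrep("N", left), sequence, strrep("N", L - n - left))
}

#' Build ortholog enhancer pairs from a region correspondence
#'
#' Aligns corresponding regions of two species, keeps pairs with identity
#' strictly above `identity_min` percent, and annotates each pair with
#' per-class model scores for both sequences, the delta model score, and
#' the log2 accessibility ratio (with pseudocount).
#'
#' @param correspondence Tibble with columns `region_a`, `region_b`.
#' @param seqs_a,seqs_b Named character vectors of region sequences.
#' @param model A trained `enhancer_model` (sequences are centre-trimmed /
#'   N-padded to the model input length for scoring).
#' @param class_id Class index or name for the delta score.
#' @param acc_a,acc_b Optional named accessibility vectors (normalized
#'   counts).
#' @param identity_min Identity threshold in percent (default 80,
#'   strict `>`).
#' @param pseudocount Pseudocount for the accessibility ratio (default 1).
#' @return An `ortholog_pairs` tibble: `region_a`, `region_b`, `identity`,
#'   `score`, `n_substitutions`, `n_indels`, `score_a`, `score_b`,
#'   `delta_score`, `delta_accessibility`, `alignment` (list-column).
#' @export
build_ortholog_pairs <- function(correspondence, seqs_a, seqs_b, model,
                                 class_id, acc_a = NULL, acc_b = NULL,
                                 identity_min = 80, pseudocount = 1) {
  if (is.character(class_id)) class_id <- match(class_id, model$class_names)
  L <- model$config$input_length
  rows <- list()
  for (i in seq_len(nrow(correspondence))) {
    ra <- correspondence$region_a[i]
    rb <- correspondence$region_b[i]
    if (!ra %in% names(seqs_a) || !rb %in% names(seqs_b)) {
      warn(paste0("sequence missing for pair ", ra, " / ", rb, "; skipped"))
      next
    }
    aln <- global_align(seqs_a[[ra]], seqs_b[[rb]])
    if (aln$identity <= identity_min) next
    sa <- pad_or_trim(seqs_a[[ra]], L)
    sb <- pad_or_trim(seqs_b[[rb]], L)
    sc <- rc_averaged_predict(model, c(sa, sb))
    da <- if (!is.null(acc_a) && !is.null(acc_b)) {
      log2((acc_a[[ra]] + pseudocount) / (acc_b[[rb]] + pseudocount))
    } else {
      NA_real_
    }
    rows[[length(rows) + 1L]] <- tibble(
      region_a = ra, region_b = rb, identity = aln$identity,
      score = aln$score, n_substitutions = nrow(aln$substitutions),
      n_indels = nrow(aln$indels),
      score_a = as.numeric(sc[1, class_id]),
      score_b = as.numeric(sc[2, class_id]),
      delta_score = as.numeric(sc[1, class_id] - sc[2, class_id]),
      delta_accessibility = da,
      alignment = list(aln)
    )
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble(region_a = character(), region_b = character(),
           identity = numeric(), score = numeric(),
           n_substitutions = integer(), n_indels = integer(),
           score_a = numeric(), score_b = numeric(), delta_score = numeric(),
           delta_accessibility = numeric(), alignment = list())
  class(out) <- c("ortholog_pairs", class(out))
  out
}

#' Per-mutation in silico effects within an ortholog pair
#'
#' Applies each point substitution between the two aligned sequences
#' individually to the first species' sequence and records the change in
#' the model score for the chosen class. Indels are reported by the
#' alignment but not individually simulated.
#'
#' @param pair One row of an `ortholog_pairs` tibble (or a list with
#'   `alignment` and the species-A sequence as `seq_a`).
#' @param seq_a The species-A sequence the alignment refers to.
#' @param model A trained `enhancer_model`.
#' @param class_id Class index or name.
#' @return A tibble: `pos_a` (0-based), `ref`, `alt`, `delta`.
#' @export
per_mutation_effects <- function(pair, seq_a, model, class_id) {
  if (is.character(class_id)) class_id <- match(class_id, model$class_names)
  aln <- if (is.data.frame(pair)) pair$alignment[[1]] else pair$alignment
  subs <- aln$substitutions
  if (nrow(subs) == 0) {
    return(tibble(pos_a = integer(), ref = character(), alt = character(),
                  delta = numeric()))
  }
  L <- model$config$input_length
  base <- pad_or_trim(seq_a, L)
  offset <- if (nchar(seq_a) > L) floor((nchar(seq_a) - L) / 2) else
    -floor((L - nchar(seq_a)) / 2)
  wt_codes <- as_code_matrix(base, L)[1, ]
  keep <- (subs$pos_a - offset) >= 0 & (subs$pos_a - offset) < L
  subs_in <- subs[keep, , drop = FALSE]
  muts <- matrix(rep(wt_codes, each = nrow(subs_in)), nrow(subs_in), L)
  p_local <- subs_in$pos_a - offset + 1L
  muts[cbind(seq_len(nrow(subs_in)), p_local)] <-
    match(subs_in$alt, DNA_BASES)
  all_codes <- rbind(matrix(wt_codes, 1L), muts)
  sc <- rc_averaged_predict(model, all_codes)[, class_id]
  tibble(pos_a = subs_in$pos_a, ref = subs_in$ref, alt = subs_in$alt,
         delta = sc[-1] - sc[1])
}

#' Pairwise Pearson correlation of region embeddings
#'
#' @param embeddings N x D matrix (rows = regions).
#' @return Symmetric N x N correlation matrix with unit diagonal;
#'   zero-variance embeddings yield 0 correlations (with a warning).
#' @export
embedding_correlation <- function(embeddings) {
  assert_that(nrow(embeddings) >= 2, "need >= 2 embeddings")
  sds <- apply(embeddings, 1, sd)
  bad <- sds < 1e-12
  if (any(bad)) warn("zero-variance embedding(s); correlations set to 0")
  cc <- suppressWarnings(cor(t(embeddings)))
  cc[is.na(cc)] <- 0
  cc[bad, ] <- 0
  cc[, bad] <- 0
  diag(cc) <- 1
  cc
}
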