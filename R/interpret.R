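# Reverse-complement column permutation for the position-major batch layout.
rc_batch_perm <- function(L) {
  p <- rep(seq_len(L), each = 4L)
  b <- rep(1:4, L)
  4L * (L - p) + (5L - b)
}

#' Convert convolutional filters to PWMs
#'
#' Generates `n_random` unique random k-mers (k = kernel width), scores
#' every filter on them (post-ReLU activation), selects the `top_k`
#' highest-activating k-mers per filter, and converts their base counts
#' into a row-normalized PWM. Activation ties are broken by generation
#' order (stable sort). The default `n_random` is a desk-scale 200,000;
#' the published scale (4,000,000) is available by argument.
#'
#' @param model A trained `enhancer_model`.
#' @param n_random Number of unique random k-mers (must be >= `top_k` and
#'   achievable in the 4^k alphabet).
#' @param top_k K-mers counted into each filter's PWM (default 100).
#' @param seed Integer seed.
#' @return A `filter_pwms` tibble: `filter`, `width`, `consensus`,
#'   `ic_center` (information-content centroid column), `n_sequences_used`,
#'   `mean_activation`, `max_activation`, and a `pwm` list-column.
#' @export
filters_to_pwms <- function(model, n_random = 200000L, top_k = 100L, seed = 1L) {
  cfg <- model$config
  K <- cfg$kernel_size
  assert_that(n_random >= top_k, "`n_random` must be >= `top_k`")
  if (log(n_random) > K * log(4)) {
    abort("cannot generate that many unique k-mers: alphabet too small")
  }
  set.seed(seed)
  codes <- matrix(sample.int(4L, n_random * K, replace = TRUE), n_random, K)
  # uniqueness via exact numeric keys (4^K fits a double for K <= 26)
  key_of <- function(mat) as.vector(mat %*% 4^(seq_len(K) - 1))
  key <- key_of(codes)
  while (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    codes[dup, ] <- sample.int(4L, length(dup) * K, replace = TRUE)
    key[dup] <- key_of(codes[dup, , drop = FALSE])
  }
  F_ <- cfg$n_filters
  act <- matrix(0, n_random, F_)
  for (b0 in seq(1L, n_random, by = 50000L)) {
    idx <- b0:min(b0 + 49999L, n_random)
    Xb <- codes_to_batch(codes[idx, , drop = FALSE])
    A <- sweep(Xb %*% model$params$Wc, 2L, model$params$bc, "+")
    A[A < 0] <- 0
    act[idx, ] <- A
  }
  out <- lapply(seq_len(F_), function(f) {
    ord <- order(act[, f], decreasing = TRUE)[seq_len(top_k)]
    counts <- vapply(seq_len(K), function(p) {
      tabulate(codes[ord, p], nbins = 4L)
    }, numeric(4))
    pwm <- t(counts) / top_k
    colnames(pwm) <- DNA_BASES
    ic <- pwm_ic(pwm)
    tibble(
      filter = f, width = K, consensus = pwm_consensus(pwm),
      ic_center = sum(ic * seq_len(K)) / max(sum(ic), 1e-12),
      n_sequences_used = top_k,
      mean_activation = mean(act[, f]),
      max_activation = max(act[, f]),
      pwm = list(pwm)
    )
  })
  structure(dplyr::bind_rows(out), class = c("filter_pwms", "tbl_df", "tbl",
                                             "data.frame"))
}

#' PWM similarity
#'
#' Maximum, over all alignment offsets and both orientations, of the
#' information-content-weighted Pearson correlation between the aligned
#' columns of two PWMs: the correlation over the flattened column
#' probabilities, with each aligned column pair weighted by the mean of
#' the two columns' information contents (weighted moments). Weighting the
#' correlation, rather than rescaling the values, keeps the measure
#' invariant to how sharp two representations of the same motif are.
#' Symmetric; `sim(p, p) = 1`; `sim(p, revcomp(p)) = 1`; comparisons with
#' only zero-IC (uniform) columns are defined as 0.
#'
#' @param a,b PWM matrices (W x 4) or one-row motif/filter tibbles.
#' @param min_overlap Minimum aligned columns. The default (`NULL`) requires
#'   75% of the shorter PWM's width (at least 4 columns), which prevents
#'   spuriously high correlations from tiny overlaps.
#' @return A list with `similarity` in `[-1, 1]`, `offset` (of `b`
#'   relative to `a`, at the best alignment) and `orientation`
#'   (`"+"`/`"-"`).
#' @export
pwm_similarity <- function(a, b, min_overlap = NULL) {
  a <- extract_pwm(a)
  b <- extract_pwm(b)
  min_overlap <- min_overlap %||%
    max(4L, as.integer(ceiling(0.75 * min(nrow(a), nrow(b)))))
  best <- list(similarity = 0, offset = 0L, orientation = "+")
  ic_a <- pwm_ic(a)
  for (orient in c("+", "-")) {
    bb <- if (orient == "+") b else pwm_rc(b)
    ic_b <- pwm_ic(bb)
    wa <- nrow(a); wb <- nrow(bb)
    for (off in (-(wb - min_overlap)):(wa - min_overlap)) {
      ia <- max(1L, 1L + off):min(wa, wb + off)
      ib <- ia - off
      w <- rep((ic_a[ia] + ic_b[ib]) / 2, each = 4L)
      if (sum(w) < 1e-9) next
      x <- as.vector(t(a[ia, , drop = FALSE]))
      y <- as.vector(t(bb[ib, , drop = FALSE]))
      mx <- sum(w * x) / sum(w)
      my <- sum(w * y) / sum(w)
      vx <- sum(w * (x - mx)^2)
      vy <- sum(w * (y - my)^2)
      if (vx < 1e-12 || vy < 1e-12) next
      r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
      if (r > best$similarity) {
        best <- list(similarity = r, offset = off, orientation = orient)
      }
    }
  }
  best
}

extract_pwm <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x) && "pwm" %in% names(x)) {
    assert_that(nrow(x) == 1, "pass a single motif row or a matrix")
    return(x$pwm[[1]])
  }
  abort("cannot extract a PWM from this object")
}

#' Match filters to a motif library
#'
#' Annotates each filter PWM with its best-matching library motif by
#' [pwm_similarity()].
#'
#' @param filter_pwms A `filter_pwms` tibble.
#' @param motifs A motif library tibble.
#' @param min_similarity Matches below this are labelled family `"other"`.
#' @return A tibble: `filter`, `motif`, `family`, `similarity`, `offset`,
#'   `orientation`.
#' @export
match_filters <- function(filter_pwms, motifs, min_similarity = 0.6) {
  out <- lapply(seq_len(nrow(filter_pwms)), function(i) {
    sims <- lapply(seq_len(nrow(motifs)), function(j) {
      s <- pwm_similarity(filter_pwms$pwm[[i]], motifs$pwm[[j]])
      tibble(motif = motifs$name[j], family = motifs$family[j],
             similarity = s$similarity, offset = s$offset,
             orientation = s$orientation)
    })
    sims <- dplyr::bind_rows(sims)
    best <- sims[which.max(sims$similarity), ]
    best$filter <- filter_pwms$filter[i]
    best$motif_width <- motifs$width[match(best$motif, motifs$name)]
    if (best$similarity < min_similarity) best$family <- "other"
    best
  })
  dplyr::bind_rows(out)[, c("filter", "motif", "family", "similarity",
                            "offset", "orientation", "motif_width")]
}

# Conv activation maps (post-ReLU, forward strand) for a set of sequences.
# Returns a list of T x F matrices.
activation_maps <- function(model, x) {
  cfg <- model$config
  codes <- as_code_matrix(x, cfg$input_length)
  T_ <- conv_positions(cfg)
  n <- nrow(codes)
  out <- vector("list", n)
  for (b0 in seq(1L, n, by = 128L)) {
    idx <- b0:min(b0 + 127L, n)
    Xb <- codes_to_batch(codes[idx, , drop = FALSE])
    cf <- conv_forward(model$params, cfg, Xb)
    B <- length(idx)
    for (k in seq_along(idx)) {
      rows <- seq(k, by = B, length.out = T_)
      out[[idx[k]]] <- cf$A1[rows, , drop = FALSE]
    }
  }
  names(out) <- if (is.character(x)) names(x) else rownames(x)
  out
}

#' Per-class filter importance by mean-ablation
#'
#' Replaces one filter's activation map with its mean activation over the
#' provided data and measures the increase in per-class binary
#' cross-entropy loss; a constant filter therefore has importance exactly
#' 0. Filters are ranked per class by descending importance.
#'
#' @param model A trained `enhancer_model`.
#' @param x Sequences (character vector).
#' @param y Binary label matrix (N x n_classes).
#' @param chunk Minibatch size for the forward passes.
#' @return A tibble: `filter`, `class`, `importance`, `rank` (1 = most
#'   important for the class).
#' @export
filter_importance <- function(model, x, y, chunk = 128L) {
  cfg <- model$config
  codes <- as_code_matrix(x, cfg$input_length)
  y <- as.matrix(y)
  n <- nrow(codes)
  F_ <- cfg$n_filters
  C_ <- cfg$n_classes
  # pass 1: mean activation per filter
  act_sum <- numeric(F_)
  act_n <- 0
  caches <- NULL
  for (b0 in seq(1L, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, n)
    Xb <- codes_to_batch(codes[idx, , drop = FALSE])
    cf <- conv_forward(model$params, cfg, Xb)
    act_sum <- act_sum + colSums(cf$A1)
    act_n <- act_n + nrow(cf$A1)
  }
  act_mean <- act_sum / act_n
  # pass 2: intact and ablated per-class losses
  class_bce <- function(p, yy) {
    p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    colSums(-(yy * log(p) + (1 - yy) * log(1 - p)))
  }
  loss_base <- numeric(C_)
  loss_abl <- matrix(0, F_, C_)
  for (b0 in seq(1L, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, n)
    Xb <- codes_to_batch(codes[idx, , drop = FALSE])
    yy <- y[idx, , drop = FALSE]
    cf <- conv_forward(model$params, cfg, Xb)
    hf <- head_forward(model$params, cfg, cf$A1, cf$B, train = FALSE,
                       want_cache = FALSE)
    loss_base <- loss_base + class_bce(hf$out, yy)
    for (f in seq_len(F_)) {
      A_abl <- cf$A1
      A_abl[, f] <- act_mean[f]
      hf2 <- head_forward(model$params, cfg, A_abl, cf$B, train = FALSE,
                          want_cache = FALSE)
      loss_abl[f, ] <- loss_abl[f, ] + class_bce(hf2$out, yy)
    }
  }
  imp <- sweep(loss_abl, 2L, loss_base, "-") / n
  out <- tidyr::crossing(filter = seq_len(F_), class = model$class_names)
  out <- out[order(match(out$class, model$class_names), out$filter), ]
  out$importance <- as.vector(imp)
  out <- out %>%
    dplyr::group_by(.data$class) %>%
    dplyr::mutate(rank = rank(-.data$importance, ties.method = "first")) %>%
    dplyr::ungroup()
  out[, c("filter", "class", "importance", "rank")]
}

# d f_c / d input for a continuous batch Xb (B x 4L), where f_c is the
# single-strand sigmoid output for class `class_id`.
grad_input_batch <- function(model, Xb, class_id) {
  cfg <- model$config
  dummy <- matrix(0, nrow(Xb), cfg$n_classes)
  res <- cpp_batch(Xb, dummy, model$params, list(), cfg$pool_size,
                   pooled_positions(cfg), TRUE, TRUE, as.integer(class_id))
  list(grad = res$dXb, score = res$out[, class_id])
}

# Strand-averaged score and input gradient for continuous inputs.
grad_input_rc_avg <- function(model, Xb, class_id, perm) {
  g1 <- grad_input_batch(model, Xb, class_id)
  g2 <- grad_input_batch(model, Xb[, perm, drop = FALSE], class_id)
  list(grad = (g1$grad + g2$grad[, perm, drop = FALSE]) / 2,
       score = (g1$score + g2$score) / 2)
}

#' Per-nucleotide attribution profile
#'
#' Attributes a class prediction to individual nucleotides by integrated
#' gradients against a set of reference sequences (expected-gradients
#' style): for each sampled reference, gradients of the strand-averaged
#' class score are averaged along the straight path from reference to
#' input (midpoint rule, `n_steps` points) and multiplied by
#' (input - reference). This satisfies the completeness contract: the
#' observed-base contributions sum to the prediction minus the mean
#' reference prediction (up to path-discretization error). Hypothetical
#' (absent-base) contributions are reported in the full matrix but never
#' enter completeness.
#'
#' @param model A trained `enhancer_model`.
#' @param sequence A single sequence of the configured input length.
#' @param class_id Class index (or name) to attribute.
#' @param references Character vector of reference sequences (the pool).
#' @param n_refs References sampled from the pool (default 20; warns and
#'   uses all if the pool is smaller).
#' @param n_steps Path integration steps per reference (default 20).
#' @param seed Integer seed for reference sampling.
#' @return An `attribution_profile`: list with `contrib` (L x 4 matrix,
#'   hypothetical-style), `observed` (contrib * one-hot), `position`
#'   (per-position totals), `score`, `reference_score`, `delta`,
#'   `residual` (completeness residual), `class_id`, `sequence`.
#' @export
attribute <- function(model, sequence, class_id, references, n_refs = 20L,
                      n_steps = 20L, seed = 1L) {
  cfg <- model$config
  assert_that(length(references) > 0, "`references` must be nonempty")
  if (is.character(class_id)) class_id <- match(class_id, model$class_names)
  if (length(references) < n_refs) {
    warn(paste0("reference pool smaller than n_refs; using all ",
                length(references)))
    n_refs <- length(references)
  }
  set.seed(seed)
  refs <- references[sample.int(length(references), n_refs)]
  L <- cfg$input_length
  perm <- rc_batch_perm(L)
  x_codes <- as_code_matrix(sequence, L)
  xb <- codes_to_batch(x_codes)          # 1 x 4L
  rb <- codes_to_batch(as_code_matrix(refs, L))  # n_refs x 4L
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  # batch all (ref, step) interpolants
  G_sum <- matrix(0, n_refs, 4L * L)
  xrep <- rb * 0
  for (i in seq_len(n_refs)) xrep[i, ] <- xb
  diff <- xrep - rb
  for (a in alphas) {
    Xi <- rb + a * diff
    g <- grad_input_rc_avg(model, Xi, class_id, perm)
    G_sum <- G_sum + g$grad
  }
  G <- G_sum / n_steps                    # n_refs x 4L mean path gradients
  # per-reference hypothetical contributions, then average over references
  contrib_mat <- matrix(0, L, 4L)
  for (i in seq_len(n_refs)) {
    Gi <- matrix(G[i, ], L, 4L, byrow = TRUE)
    Ri <- matrix(rb[i, ], L, 4L, byrow = TRUE)
    dot_i <- rowSums(Gi * Ri)
    contrib_mat <- contrib_mat + (Gi - dot_i)
  }
  contrib_mat <- contrib_mat / n_refs
  onehot <- matrix(xb[1, ], L, 4L, byrow = TRUE)
  colnames(contrib_mat) <- DNA_BASES
  observed <- contrib_mat * onehot
  score <- as.numeric(rc_averaged_predict(model, sequence)[1, class_id])
  ref_scores <- rc_averaged_predict(model, refs)[, class_id]
  delta <- score - mean(ref_scores)
  total <- sum(observed)
  structure(
    list(contrib = contrib_mat, observed = observed,
         position = rowSums(observed), score = score,
         reference_score = mean(ref_scores), delta = delta,
         residual = abs(total - delta), class_id = class_id,
         sequence = sequence, n_refs = n_refs, n_steps = n_steps),
    class = "attribution_profile"
  )
}

#' @export
print.attribution_profile <- function(x, ...) {
  cat("<attribution_profile> class ", x$class_id, ": score ",
      round(x$score, 4), ", delta vs refs ", round(x$delta, 4),
      ", completeness residual ", signif(x$residual, 3), "\n", sep = "")
  invisible(x)
}

#' In silico saturation mutagenesis
#'
#' Scores every possible single-nucleotide substitution of the sequence
#' and records, per class, the change in the strand-averaged prediction
#' relative to wild type. Reference-base cells are exactly 0.
#'
#' @param model A trained `enhancer_model`.
#' @param sequence A sequence of the configured input length.
#' @param classes Class indices or names (default: all).
#' @return A `mutagenesis_map`: list with `delta` (L x 4 x n_classes
#'   array), `wt_scores`, `classes`, `sequence`.
#' @export
saturation_mutagenesis <- function(model, sequence, classes = NULL) {
  cfg <- model$config
  L <- cfg$input_length
  classes <- classes %||% seq_len(cfg$n_classes)
  if (is.character(classes)) classes <- match(classes, model$class_names)
  wt <- as_code_matrix(sequence, L)[1, ]
  muts <- matrix(rep(wt, each = 3L * L), 3L * L, L, byrow = FALSE)
  pos <- rep(seq_len(L), each = 3L)
  alts <- unlist(lapply(wt, function(b) setdiff(1:4, b)))
  muts[cbind(seq_len(3L * L), pos)] <- alts
  all_codes <- rbind(matrix(wt, 1L), muts)
  scores <- rc_averaged_predict(model, all_codes)
  wt_scores <- scores[1, ]
  delta <- array(0, dim = c(L, 4L, length(classes)),
                 dimnames = list(NULL, DNA_BASES, model$class_names[classes]))
  for (ci in seq_along(classes)) {
    d <- scores[-1, classes[ci]] - wt_scores[classes[ci]]
    delta[cbind(pos, alts, ci)] <- d
  }
  structure(
    list(delta = delta, wt_scores = wt_scores, classes = classes,
         class_names = model$class_names[classes], sequence = sequence),
    class = "mutagenesis_map"
  )
}

#' @export
print.mutagenesis_map <- function(x, ...) {
  cat("<mutagenesis_map> ", dim(x$delta)[1], " bp x ", length(x$classes),
      " classes; largest |delta| ", signif(max(abs(x$delta)), 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mutagenesis_map <- function(x, ...) {
  L <- dim(x$delta)[1]
  wt <- encode_sequence(x$sequence)
  out <- tidyr::crossing(class = x$class_names, position = seq_len(L),
                         alt = DNA_BASES)
  out$ref <- DNA_BASES[pmax(wt[out$position], 1L)]
  ci <- match(out$class, x$class_names)
  out$delta <- x$delta[cbind(out$position, match(out$alt, DNA_BASES), ci)]
  out[out$ref != out$alt, c("position", "ref", "alt", "class", "delta")]
}

# Raw motif-instance scores for one sequence: conv activation (post-ReLU)
# times the attribution window sum, per filter and alignment position.
# Both strands are scored (a filter detects one orientation of a motif;
# minus-strand instances appear on the reverse complement): rows 1..T are
# forward-strand alignment positions, rows T+1..2T the reverse strand.
filter_attr_scores <- function(model, sequence, position_attr) {
  cfg <- model$config
  K <- cfg$kernel_size
  win_of <- function(attr_vec, T_) {
    cs <- cumsum(c(0, attr_vec))
    cs[seq_len(T_) + K] - cs[seq_len(T_)]
  }
  act_f <- activation_maps(model, sequence)[[1]]   # T x F
  T_ <- nrow(act_f)
  rc_seq <- reverse_complement(unname(sequence))
  act_r <- activation_maps(model, rc_seq)[[1]]
  rbind(act_f * win_of(position_attr, T_),
        act_r * win_of(rev(position_attr), T_))
}

#' Calibrate per-filter motif-instance thresholds
#'
#' Computes raw instance scores (filter activation multiplied by the
#' attribution window sum) on a positive-class corpus and a contrast
#' corpus, min-max normalizes per filter over the combined corpus, and
#' chooses a per-filter threshold separating the two corpora. The default
#' method fixes the threshold where only a small fraction (`fpr`) of
#' contrast-corpus positions exceed it — a fixed-specificity rule that is
#' well behaved when most positive-corpus positions are background.
#' `method = "youden"` instead maximizes Youden's J over the pooled
#' position scores. The contrast corpus should carry real attributions
#' for its own class (not near-zero attributions for the positive class),
#' so that a filter firing on other classes' motif instances enters the
#' negative distribution and is thresholded away.
#'
#' @param model A trained `enhancer_model`.
#' @param pos_sequences,neg_sequences Named character vectors of
#'   positive-class and contrast-class sequences.
#' @param pos_attr,neg_attr Lists of per-position attribution vectors (or
#'   `attribution_profile` objects), aligned with the sequences.
#' @param method `"specificity"` (default) or `"youden"`.
#' @param fpr Tolerated fraction of contrast positions above the
#'   threshold (default 0.003).
#' @return A `motif_scan_calibration` tibble: `filter`, `score_min`,
#'   `score_max`, `threshold`, `youden`.
#' @export
calibrate_motif_thresholds <- function(model, pos_sequences, pos_attr,
                                       neg_sequences, neg_attr,
                                       method = c("specificity", "youden"),
                                       fpr = 0.003) {
  method <- match.arg(method)
  get_attr <- function(a) if (inherits(a, "attribution_profile")) a$position else a
  F_ <- model$config$n_filters
  raw_of <- function(seqs, attrs) {
    lapply(seq_along(seqs), function(i) {
      filter_attr_scores(model, seqs[i], get_attr(attrs[[i]]))
    })
  }
  pos_raw <- raw_of(pos_sequences, pos_attr)
  neg_raw <- raw_of(neg_sequences, neg_attr)
  out <- lapply(seq_len(F_), function(f) {
    pv <- unlist(lapply(pos_raw, function(R) R[, f]))
    nv <- unlist(lapply(neg_raw, function(R) R[, f]))
    lo <- min(pv, nv)
    hi <- max(pv, nv)
    rng <- max(hi - lo, 1e-12)
    p <- (pv - lo) / rng
    q <- (nv - lo) / rng
    if (method == "specificity") {
      th <- unname(stats::quantile(q, 1 - fpr))
      jv <- mean(p > th) - mean(q > th)
    } else {
      cand <- unique(stats::quantile(c(p, q), seq(0.8, 0.99995,
                                                  length.out = 500)))
      j <- vapply(cand, function(th) {
        mean(p > th) - mean(q > th)
      }, numeric(1))
      best <- which.max(j)
      th <- unname(cand[best])
      jv <- unname(j[best])
    }
    tibble(filter = f, score_min = lo, score_max = hi,
           threshold = th, youden = jv)
  })
  structure(dplyr::bind_rows(out),
            class = c("motif_scan_calibration", "tbl_df", "tbl", "data.frame"))
}

#' Locate motif instances with attribution-gated filter scanning
#'
#' Emits a motif hit where a filter's normalized instance score exceeds
#' its calibrated threshold (strictly; ties at the threshold are
#' excluded). Raw scores are the product of the filter activation and the
#' attribution window sum; normalization uses the calibration min-max.
#' Overlapping candidate positions of the same filter are reduced by
#' non-maximum suppression. Hit centers are corrected by the filter PWM's
#' information-content centroid so they align with the underlying motif
#' core.
#'
#' @param model A trained `enhancer_model`.
#' @param sequences Named character vector.
#' @param attributions List of per-position attribution vectors or
#'   `attribution_profile`s, aligned with `sequences`.
#' @param calibration A `motif_scan_calibration` (required).
#' @param filter_pwms Optional `filter_pwms` for center correction and
#'   consensus annotation.
#' @param filter_families Optional tibble from [match_filters()]; annotates
#'   hits with motif families, and refines hit centers using the filter's
#'   alignment offset to its matched motif (more accurate than the IC
#'   centroid when the motif sits off-centre in the filter window).
#' @param filters Optional subset of filter ids to scan (e.g. one
#'   representative filter per family); default all.
#' @param nms_sep Minimum separation (bp) between retained hits of the
#'   same filter (default: the kernel width).
#' @return A tibble of hits: `region`, `filter`, `family`, `start`, `end`
#'   (0-based half-open, filter window), `center`, `strand`, `raw`,
#'   `norm`, `passes_threshold`.
#' @export
scan_motif_instances <- function(model, sequences, attributions, calibration,
                                 filter_pwms = NULL, filter_families = NULL,
                                 filters = NULL, nms_sep = NULL) {
  assert_that(!missing(calibration) && !is.null(calibration),
              "a calibration (see calibrate_motif_thresholds) is required")
  get_attr <- function(a) if (inherits(a, "attribution_profile")) a$position else a
  cfg <- model$config
  K <- cfg$kernel_size
  F_ <- cfg$n_filters
  nms_sep <- nms_sep %||% K
  filters <- filters %||% seq_len(F_)
  centers <- rep((K + 1) / 2, F_)
  if (!is.null(filter_pwms)) {
    centers[filter_pwms$filter] <- filter_pwms$ic_center
  }
  fam <- rep(NA_character_, F_)
  if (!is.null(filter_families)) {
    fam[filter_families$filter] <- filter_families$family
    # centre of the matched motif inside the filter window (1-based)
    # the matched motif occupies filter columns offset+1 .. offset+width
    # in either orientation, so its centre is orientation-independent
    ok <- !is.na(filter_families$offset) & filter_families$family != "other"
    ctr <- filter_families$offset + filter_families$motif_width / 2 + 0.5
    centers[filter_families$filter[ok]] <- ctr[ok]
  }
  L <- cfg$input_length
  T_ <- conv_positions(cfg)
  out <- list()
  for (i in seq_along(sequences)) {
    raw <- filter_attr_scores(model, sequences[i], get_attr(attributions[[i]]))
    for (f in filters) {
      cal <- calibration[calibration$filter == f, ]
      rng <- max(cal$score_max - cal$score_min, 1e-12)
      norm <- (raw[, f] - cal$score_min) / rng
      cand <- which(norm > cal$threshold)
      if (length(cand) == 0) next
      # map stacked rows to forward-strand coordinates
      is_rc <- cand > T_
      p_loc <- ifelse(is_rc, cand - T_, cand)
      center <- ifelse(is_rc,
                       L - p_loc - centers[f] + 1,
                       p_loc - 1 + centers[f] - 1)
      start <- ifelse(is_rc, L - p_loc + 1L - K, p_loc - 1L)
      # non-maximum suppression across both strands by centre distance
      ord <- order(norm[cand], decreasing = TRUE)
      keep <- logical(length(cand))
      kept_centers <- numeric(0)
      for (j in ord) {
        if (all(abs(kept_centers - center[j]) >= nms_sep)) {
          keep[j] <- TRUE
          kept_centers <- c(kept_centers, center[j])
        }
      }
      k_start <- as.integer(start[keep])
      k_center <- center[keep]
      k_strand <- ifelse(is_rc[keep], "-", "+")
      k_rows <- cand[keep]
      out[[length(out) + 1L]] <- tibble(
        region = names(sequences)[i] %||% paste0("seq_", i),
        filter = f,
        family = fam[f],
        start = k_start,
        end = k_start + K,
        center = k_center,
        strand = k_strand,
        raw = raw[k_rows, f],
        norm = norm[k_rows],
        passes_threshold = TRUE
      ) %>% dplyr::arrange(.data$start)
    }
  }
  if (length(out) == 0) {
    return(tibble(region = character(), filter = integer(),
                  family = character(), start = integer(), end = integer(),
                  center = numeric(), strand = character(), raw = numeric(),
                  norm = numeric(), passes_threshold = logical()))
  }
  dplyr::bind_rows(out)
}

#' Reduce motif hits to one per motif instance within a family
#'
#' Hits of the same family whose centers are closer than `min_sep` bp are
#' merged, keeping the highest-normalized-score hit.
#'
#' @param hits A hit tibble from [scan_motif_instances()].
#' @param min_sep Minimum center separation in bp (default 8).
#' @return The deduplicated hit tibble.
#' @export
dedupe_hits <- function(hits, min_sep = 8) {
  hits %>%
    dplyr::group_by(.data$region, .data$family) %>%
    dplyr::arrange(dplyr::desc(.data$norm), .by_group = TRUE) %>%
    dplyr::group_modify(function(df, key) {
      kept <- integer(0)
      sel <- logical(nrow(df))
      for (i in seq_len(nrow(df))) {
        if (all(abs(df$center[kept] - df$center[i]) >= min_sep)) {
          kept <- c(kept, i)
          sel[i] <- TRUE
        }
      }
      df[sel, , drop = FALSE]
    }) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$region, .data$start)
}

#' Write motif hits as BED6
#'
#' The normalized score is scaled by 1000 and clamped to `[0, 1000]`.
#'
#' @param hits A hit tibble (with `region` used as the chromosome field).
#' @param path Output path.
#' @export
write_hits_bed <- function(hits, path) {
  write_bed(tibble(
    chrom = hits$region, start = hits$start, end = hits$end,
    name = ifelse(is.na(hits$family), paste0("filter_", hits$filter),
                  hits$family),
    score = pmin(pmax(round(hits$norm * 1000), 0), 1000),
    strand = hits$strand
  ), path)
}
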