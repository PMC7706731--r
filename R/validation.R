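# The bundled validation study: fixed synthetic designs exercising motif
# recovery, instance localization and cross-species effect attribution
# against generator ground truth. Used by the test suite and by
# scripts/acceptance.R; all sizes are desk scale (see the methods
# vignette).

#' Motif families of the recovery study
#'
#' One class per family, so that each family's filters are necessary for
#' classification and can be ranked by per-class importance.
#' @export
recovery_families <- c("SOX_dimer", "MITF_ebox", "TFAP2A", "RUNX", "AP1",
                       "TEAD")

recovery_family_names <- c("SOX", "MITF", "TFAP2A", "RUNX", "AP1", "TEAD")

#' Class specs of the single-family recovery cohort
#'
#' Six classes, one motif family each (two instances per 150-bp region,
#' placed in the central window).
#'
#' @param n_regions Regions per class (default 300).
#' @param region_length Region length (default 150).
#' @return A list of `class_spec`s.
#' @export
recovery_specs <- function(n_regions = 300L, region_length = 150L) {
  lapply(seq_along(recovery_families), function(i) {
    class_spec(i, recovery_families[i],
               motifs = tibble(motif = recovery_families[i], count = 2,
                               window_start = 25L,
                               window_end = region_length - 25L),
               n_regions = n_regions, region_length = region_length)
  })
}

#' Run one motif-recovery study
#'
#' Simulates the single-family cohort, trains a reduced model (16
#' filters, 150-bp input, 32 epochs), converts filters to PWMs and
#' computes per-class filter importances.
#'
#' @param seed Integer seed (cohort seed is `1000 + seed`).
#' @param epochs Training epochs (default 32; the desk dataset sees ~28
#'   updates per epoch).
#' @param n_random Random k-mers for the filter-to-PWM conversion.
#' @return A list: `cohort`, `model`, `filter_pwms`, `importance`, `seed`.
#' @export
recovery_run <- function(seed, epochs = 32L, n_random = 1000000L) {
  cohort_seed <- as.integer((1000 + as.numeric(seed)) %% 2147483629)
  coh <- simulate_regions(recovery_specs(), seed = cohort_seed)
  cfg <- desk_config(n_classes = length(recovery_families),
                     n_filters = 16L, input_length = 150L, seed = seed)
  m <- build_model(cfg, class_names = coh$classes)
  m <- train_model(m, coh$sequences, coh$label_matrix, epochs = epochs)
  fp <- filters_to_pwms(m, n_random = n_random, seed = seed)
  sub <- unlist(lapply(coh$classes, function(cl) {
    which(coh$regions$class == cl)[1:30]
  }))
  imp <- filter_importance(m, coh$sequences[sub],
                           coh$label_matrix[sub, , drop = FALSE])
  list(cohort = coh, model = m, filter_pwms = fp, importance = imp,
       seed = seed)
}

#' Summarize motif recovery for one run
#'
#' Per family: the best filter-PWM similarity to the implanted PWM, and
#' whether some filter achieves both `similarity >= sim_min` and
#' importance rank `<= rank_max` for the family's class.
#'
#' @param run A [recovery_run()] result.
#' @param sim_min,rank_max Joint criterion parameters.
#' @return A tibble: `family`, `best_sim`, `joint_ok`.
#' @export
recovery_stats <- function(run, sim_min = 0.75, rank_max = 3) {
  lib <- motif_library()
  out <- lapply(recovery_families, function(fam) {
    tp <- lib$pwm[[which(lib$name == fam)]]
    sims <- vapply(run$filter_pwms$pwm, function(p) {
      pwm_similarity(p, tp)$similarity
    }, numeric(1))
    imp_f <- run$importance[run$importance$class == fam, ]
    ranks <- imp_f$rank[order(imp_f$filter)]
    tibble(family = fam, best_sim = max(sims),
           joint_ok = any(sims >= sim_min & ranks <= rank_max))
  })
  dplyr::bind_rows(out)
}

# Representative filter per family: among well-matching filters, prefer
# one whose alignment keeps the whole motif inside the filter window
# (edge-aligned matches localize instance centres poorly).
family_representatives <- function(run) {
  lib <- motif_library()
  K <- run$model$config$kernel_size
  dplyr::bind_rows(lapply(seq_along(recovery_families), function(j) {
    tp <- lib[lib$name == recovery_families[j], ]
    sims <- lapply(run$filter_pwms$pwm, function(p) {
      pwm_similarity(p, tp$pwm[[1]])
    })
    vals <- vapply(sims, `[[`, numeric(1), "similarity")
    offs <- vapply(sims, `[[`, numeric(1), "offset")
    full <- offs >= 0 & offs + tp$width <= K
    pool <- which(vals >= 0.7 & full)
    b <- if (length(pool) > 0) pool[which.max(vals[pool])] else which.max(vals)
    tibble(filter = run$filter_pwms$filter[b], motif = tp$name,
           family = recovery_family_names[j], similarity = vals[b],
           offset = sims[[b]]$offset, orientation = sims[[b]]$orientation,
           motif_width = tp$width)
  }))
}

#' Locate motif instances on the recovery cohort
#'
#' Per family, the family's class regions are scanned with its
#' representative filter; thresholds are calibrated against the other
#' classes carrying their own-class attributions.
#'
#' @param run A [recovery_run()] result.
#' @param per_class Regions scanned per class (default 10).
#' @param n_refs,n_steps Attribution parameters.
#' @return A list: `hits` (tibble), `truth` (generator truth for the
#'   scanned regions).
#' @export
recovery_scan <- function(run, per_class = 10L, n_refs = 10L, n_steps = 10L) {
  coh <- run$cohort
  m <- run$model
  scan_idx <- unlist(lapply(coh$classes, function(cl) {
    which(coh$regions$class == cl)[seq_len(per_class)]
  }))
  set.seed(run$seed)
  refs <- coh$sequences[sample(length(coh$sequences), 100L)]
  attrs <- lapply(scan_idx, function(i) {
    attribute(m, coh$sequences[[i]], coh$regions$class[i], refs,
              n_refs = n_refs, n_steps = n_steps, seed = i)
  })
  classes_of <- coh$regions$class[scan_idx]
  reps <- family_representatives(run)
  hits <- list()
  for (j in seq_along(recovery_families)) {
    own <- classes_of == recovery_families[j]
    cal <- calibrate_motif_thresholds(
      m, coh$sequences[scan_idx[own]], attrs[own],
      coh$sequences[scan_idx[!own]], attrs[!own]
    )
    hits[[j]] <- scan_motif_instances(
      m, coh$sequences[scan_idx[own]], attrs[own], cal,
      filter_pwms = run$filter_pwms, filter_families = reps,
      filters = reps$filter[j], nms_sep = 14L
    )
  }
  truth <- coh$truth_hits[coh$truth_hits$region %in%
                            coh$regions$name[scan_idx], ]
  list(hits = dplyr::bind_rows(hits), truth = truth)
}

#' Recall and precision of motif hits against implanted truth
#'
#' A truth instance is recovered when a same-family hit centre lies
#' within `tol` bp of the instance centre; a hit is correct when it
#' matches some same-family truth instance the same way.
#'
#' @param hits Hit tibble (with `region`, `family`, `center`).
#' @param truth Generator truth tibble.
#' @param tol Centre tolerance in bp (default 2).
#' @return A list: `recall`, `precision`, `n_truth`, `n_hits`.
#' @export
scan_match_stats <- function(hits, truth, tol = 2) {
  truth$center <- (truth$start + truth$end - 1) / 2
  matched_truth <- vapply(seq_len(nrow(truth)), function(i) {
    h <- hits[hits$region == truth$region[i] &
                hits$family == truth$family[i], ]
    nrow(h) > 0 && any(abs(h$center - truth$center[i]) <= tol)
  }, logical(1))
  matched_hits <- vapply(seq_len(nrow(hits)), function(j) {
    t <- truth[truth$region == hits$region[j] &
                 truth$family == hits$family[j], ]
    nrow(t) > 0 && any(abs(t$center - hits$center[j]) <= tol)
  }, logical(1))
  list(recall = mean(matched_truth), precision = mean(matched_hits),
       n_truth = nrow(truth), n_hits = nrow(hits))
}

#' Engineered motif-loss pairs: is the top mutation inside the lost site?
#'
#' For each region with a SOX-family instance, builds a partner sequence
#' with one randomized SOX instance plus scattered background
#' substitutions, aligns the pair, simulates each point mutation, and
#' checks whether the largest single-mutation |delta| lies inside the
#' lost instance.
#'
#' @param model A trained `enhancer_model`.
#' @param cohort A cohort subset (list with `sequences`, `truth_hits`).
#' @param seed Integer seed.
#' @param n_bg_subs Background substitutions per partner (default 8).
#' @param class_id Class scored (default `"MEL"`).
#' @return The fraction of pairs whose top mutation falls inside the
#'   lost instance.
#' @export
engineered_loss_hit_rate <- function(model, cohort, seed = 1L,
                                     n_bg_subs = 8L, class_id = "MEL") {
  set.seed(seed)
  ids <- names(cohort$sequences)
  hit_in <- logical(0)
  for (r in ids) {
    th <- cohort$truth_hits[cohort$truth_hits$region == r &
                              cohort$truth_hits$family == "SOX", ]
    if (nrow(th) == 0) next
    pick <- th[sample.int(nrow(th), 1L), ]
    codes <- encode_sequence(cohort$sequences[[r]])
    span <- (pick$start + 1L):pick$end
    codes[span] <- 1L + (codes[span] + sample.int(3L, length(span),
                                                  replace = TRUE) - 1L) %% 4L
    all_motif <- unlist(mapply(
      function(s, e) (s + 1):e,
      cohort$truth_hits$start[cohort$truth_hits$region == r],
      cohort$truth_hits$end[cohort$truth_hits$region == r],
      SIMPLIFY = FALSE
    ))
    free <- setdiff(seq_along(codes), all_motif)
    bg <- sample(free, n_bg_subs)
    codes[bg] <- 1L + (codes[bg] + sample.int(3L, n_bg_subs,
                                              replace = TRUE) - 1L) %% 4L
    partner <- decode_codes(codes)
    pair <- build_ortholog_pairs(
      tibble(region_a = r, region_b = r),
      setNames(cohort$sequences[r], r), setNames(partner, r), model,
      class_id = class_id
    )
    if (nrow(pair) == 0) next
    eff <- per_mutation_effects(pair[1, ], cohort$sequences[[r]], model,
                                class_id)
    if (nrow(eff) == 0) next
    best <- eff$pos_a[which.max(abs(eff$delta))]
    hit_in <- c(hit_in, best >= pick$start && best < pick$end)
  }
  mean(hit_in)
}
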