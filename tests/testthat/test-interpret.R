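test_that("a zero-weight filter yields a near-uniform PWM", {
  m <- build_model(tiny_config())
  m$params$Wc[, 1] <- 0
  m$params$bc[1] <- 0
  fp <- filters_to_pwms(m, n_random = 5000L, top_k = 100L, seed = 2L)
  pwm <- fp$pwm[[1]]
  # 3 sigma of a binomial(100, 0.25) proportion
  expect_true(all(abs(pwm - 0.25) <= 3 * sqrt(0.25 * 0.75 / 100)))
})

test_that("selecting every k-mer reproduces background frequencies", {
  m <- build_model(tiny_config())
  fp <- filters_to_pwms(m, n_random = 2000L, top_k = 2000L, seed = 3L)
  for (i in 1:2) {
    expect_true(all(abs(fp$pwm[[i]] - 0.25) < 0.04))
  }
})

test_that("a log-odds-engineered filter recovers its source PWM", {
  truth <- motif_model("EBOX", consensus = "TCACGTGA", p = 0.95)$pwm[[1]]
  m <- build_model(tiny_config())
  lo <- enhancerkit:::pwm_log_odds(truth)[, 1:4]
  W <- matrix(0, 4 * 12, 1)
  off <- 2L  # embed the 8-wide motif at kernel offset 2
  for (k in 1:8) W[(4 * (off + k - 2) + 1):(4 * (off + k - 2) + 4), 1] <- lo[k, ]
  m$params$Wc[, 1] <- W
  m$params$bc[1] <- 0
  fp <- filters_to_pwms(m, n_random = 60000L, top_k = 100L, seed = 4L)
  sim <- pwm_similarity(fp$pwm[[1]], truth)
  expect_gte(sim$similarity, 0.9)
})

test_that("filters_to_pwms guards its preconditions", {
  m <- build_model(tiny_config())
  expect_error(filters_to_pwms(m, n_random = 10L, top_k = 100L), "top_k")
  cfg_small <- tiny_config(kernel_size = 4L)
  m2 <- build_model(cfg_small)
  expect_error(filters_to_pwms(m2, n_random = 10^6, top_k = 100L),
               "alphabet")
})

test_that("PWM similarity is reflexive, orientation-max and zero on uniform", {
  lib <- motif_library()
  for (i in seq_len(nrow(lib))) {
    p <- lib$pwm[[i]]
    expect_equal(pwm_similarity(p, p)$similarity, 1, tolerance = 1e-9)
    expect_equal(pwm_similarity(p, enhancerkit:::pwm_rc(p))$similarity, 1,
                 tolerance = 1e-9)
  }
  uni <- matrix(0.25, 8, 4)
  expect_equal(pwm_similarity(uni, lib$pwm[[1]])$similarity, 0,
               tolerance = 1e-9)
  # symmetry
  a <- lib$pwm[[1]]; b <- lib$pwm[[2]]
  expect_equal(pwm_similarity(a, b)$similarity,
               pwm_similarity(b, a)$similarity, tolerance = 1e-9)
})

test_that("a constant filter has exactly zero importance everywhere", {
  m <- tiny_model()
  m$params$Wc[, 2] <- 0
  m$params$bc[2] <- 0
  coh <- tiny_cohort()
  idx <- seq(1, 120, by = 6)
  imp <- filter_importance(m, coh$sequences[idx], coh$label_matrix[idx, ])
  expect_true(all(is.finite(imp$importance)))
  expect_equal(imp$importance[imp$filter == 2], rep(0, 2))
  # ranking is a permutation of filters per class
  for (cl in unique(imp$class)) {
    expect_setequal(imp$rank[imp$class == cl],
                    seq_len(m$config$n_filters))
  }
})

test_that("attribution satisfies the completeness contract", {
  m <- tiny_model()
  coh <- tiny_cohort()
  refs <- coh$sequences[coh$regions$class == "BG"]
  mel <- coh$sequences[coh$regions$class == "MEL"]
  for (i in 1:4) {
    att <- attribute(m, mel[[i]], "MEL", refs, n_refs = 10L, n_steps = 10L,
                     seed = i)
    tol <- 0.05 * max(abs(att$delta), 0.01)
    expect_lte(att$residual, tol)
    # observed matrix is the contribution matrix gated by the one-hot
    oh <- one_hot(mel[[i]])
    expect_equal(att$observed, att$contrib * oh, ignore_attr = TRUE)
  }
})

test_that("reference-drawn inputs have near-zero mean total attribution", {
  m <- tiny_model()
  coh <- tiny_cohort()
  refs <- coh$sequences[coh$regions$class == "BG"]
  totals <- vapply(1:8, function(i) {
    att <- attribute(m, refs[[i]], "MEL", refs[-i], n_refs = 8L,
                     n_steps = 8L, seed = i)
    sum(att$observed)
  }, numeric(1))
  expect_lte(abs(mean(totals)), 0.01)
})

test_that("attribution warns when the reference pool is small", {
  m <- tiny_model()
  coh <- tiny_cohort()
  expect_warning(
    attribute(m, coh$sequences[[1]], "MEL", coh$sequences[2:4],
              n_refs = 10L, n_steps = 4L),
    "pool smaller"
  )
  expect_error(attribute(m, coh$sequences[[1]], "MEL", character(0)),
               "nonempty")
})

test_that("saturation mutagenesis zeroes reference cells and is involutive", {
  m <- tiny_model()
  coh <- tiny_cohort()
  s <- coh$sequences[[1]]
  mm <- saturation_mutagenesis(m, s)
  wt <- enhancerkit:::encode_sequence(s)
  for (cl in 1:2) {
    expect_equal(mm$delta[cbind(seq_along(wt), wt, cl)],
                 rep(0, length(wt)))
  }
  # apply a mutation; the reverse mutation's delta is the exact negative
  pos <- 40L
  alt <- setdiff(1:4, wt[pos])[1]
  mut_codes <- wt
  mut_codes[pos] <- alt
  mut_seq <- enhancerkit:::decode_codes(mut_codes)
  mm2 <- saturation_mutagenesis(m, mut_seq)
  expect_equal(mm2$delta[pos, wt[pos], 1], -mm$delta[pos, alt, 1],
               tolerance = 1e-12)
  # tidy output covers 3L rows per class with matching wild types
  td <- tidy(mm)
  expect_equal(nrow(td), 3 * nchar(s) * 2)
  expect_true(all(td$ref != td$alt))
})

test_that("zero attribution silences the motif scanner", {
  m <- tiny_model()
  coh <- tiny_cohort()
  s <- coh$sequences[1]
  cal <- tibble::tibble(filter = seq_len(m$config$n_filters), score_min = 0,
                        score_max = 1, threshold = 0.1, youden = 1)
  hits <- scan_motif_instances(m, s, list(rep(0, 200)), cal)
  expect_equal(nrow(hits), 0L)
  expect_error(scan_motif_instances(m, s, list(rep(0, 200)), NULL),
               "calibration")
})

test_that("scanning implanted motifs emits in-range, thresholded hits", {
  m <- tiny_model()
  coh <- tiny_cohort()
  mel_idx <- which(coh$regions$class == "MEL")[1:6]
  bg_idx <- which(coh$regions$class == "BG")[1:6]
  refs <- coh$sequences[coh$regions$class == "BG"][30:50]
  attr_of <- function(idx, cls) {
    lapply(idx, function(i) attribute(m, coh$sequences[[i]], cls, refs,
                                      n_refs = 8L, n_steps = 8L, seed = i))
  }
  mel_attr <- attr_of(mel_idx, "MEL")
  bg_attr <- attr_of(bg_idx, "MEL")
  cal <- calibrate_motif_thresholds(m, coh$sequences[mel_idx], mel_attr,
                                    coh$sequences[bg_idx], bg_attr)
  expect_equal(nrow(cal), m$config$n_filters)
  expect_true(all(cal$threshold >= 0 & cal$threshold <= 1))
  fp <- filters_to_pwms(m, n_random = 20000L, seed = 5L)
  hits <- scan_motif_instances(m, coh$sequences[mel_idx], mel_attr, cal,
                               filter_pwms = fp)
  if (nrow(hits) > 0) {
    expect_true(all(hits$start >= 0 & hits$end <= 200))
    expect_true(all(hits$norm > 0))
    expect_true(all(hits$passes_threshold))
  }
  # dedupe keeps at most one hit per family within min_sep
  hits$family <- "X"
  dd <- dedupe_hits(hits, min_sep = 8)
  for (r in unique(dd$region)) {
    centers <- sort(dd$center[dd$region == r])
    if (length(centers) > 1) expect_true(all(diff(centers) >= 8))
  }
})
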