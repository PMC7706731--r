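# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# A tiny two-class cohort (motif-rich vs background) on short regions.
tiny_specs <- function(n_regions = 60L, region_length = 200L) {
  list(
    class_spec(1L, "MEL",
               motifs = tibble::tibble(
                 motif = c("SOX_dimer", "MITF_ebox"), count = c(1, 1),
                 window_start = 30L, window_end = region_length - 30L
               ),
               n_regions = n_regions, region_length = region_length),
    class_spec(2L, "BG", motifs = NULL, n_regions = n_regions,
               region_length = region_length)
  )
}

tiny_cohort <- function() {
  memo("tiny_cohort", function() {
    simulate_regions(tiny_specs(), seed = 42L)
  })
}

tiny_config <- function(...) {
  defaults <- list(n_filters = 12L, kernel_size = 12L, pool_size = 8L,
                   pool_stride = 8L, position_dense_units = 12L,
                   recurrent_units = 12L, dense_units = 24L, n_classes = 2L,
                   input_length = 200L, batch_size = 32L, seed = 5L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# A small trained model on the tiny cohort (used by interpretation tests).
tiny_model <- function() {
  memo("tiny_model", function() {
    coh <- tiny_cohort()
    m <- build_model(tiny_config(), class_names = coh$classes)
    train_model(m, coh$sequences, coh$label_matrix, epochs = 4L)
  })
}

random_dna <- function(n, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}
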