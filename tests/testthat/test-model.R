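test_that("configuration validates sizes, dropouts and pooling arithmetic", {
  cfg <- model_config()
  expect_equal(cfg$n_filters, 128L)
  expect_equal(cfg$kernel_size, 20L)
  expect_equal(cfg$dense_units, 256L)
  expect_equal(cfg$n_classes, 24L)
  expect_equal(enhancerkit:::conv_positions(cfg), 481L)
  expect_equal(enhancerkit:::pooled_positions(cfg), 48L)
  expect_error(model_config(recurrent_dropout = 1.2), "dropout")
  expect_error(model_config(n_filters = 0), "size parameters")
  expect_error(model_config(pool_size = 10, pool_stride = 5),
               "non-overlapping")
})

test_that("the output layer has one sigmoid unit per class", {
  cfg <- tiny_config()
  m <- build_model(cfg)
  expect_equal(ncol(m$params$Wo), cfg$n_classes)
  expect_length(m$params$bo, cfg$n_classes)
  x <- random_dna(3, cfg$input_length, seed = 1)
  p <- rc_averaged_predict(m, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(dim(p), c(3L, cfg$n_classes))
})

test_that("builds are deterministic given the seed", {
  m1 <- build_model(tiny_config())
  m2 <- build_model(tiny_config())
  expect_identical(m1$params, m2$params)
  m3 <- build_model(tiny_config(seed = 6L))
  expect_false(identical(m1$params, m3$params))
  expect_error(build_model(model_config(input_length = 10, kernel_size = 20)),
               "input_length")
})

test_that("a zeroed output layer predicts exactly 0.5 everywhere", {
  m <- build_model(tiny_config())
  m$params$Wo[] <- 0
  m$params$bo[] <- 0
  p <- rc_averaged_predict(m, random_dna(2, 200, seed = 2))
  expect_equal(as.vector(p), rep(0.5, 4))
})

test_that("predictions and embeddings are exactly strand-symmetric", {
  m <- tiny_model()
  x <- random_dna(25, 200, seed = 3)
  rc <- reverse_complement(x)
  expect_equal(rc_averaged_predict(m, x), rc_averaged_predict(m, rc),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(extract_embedding(m, x), extract_embedding(m, rc),
               ignore_attr = TRUE, tolerance = 1e-12)
  # wrong length errors
  expect_error(rc_averaged_predict(m, "ACGT"), "length")
})

test_that("backpropagation matches numerical gradients", {
  set.seed(44)
  cfg <- model_config(n_filters = 3L, kernel_size = 5L, pool_size = 3L,
                      pool_stride = 3L, position_dense_units = 4L,
                      recurrent_units = 3L, dense_units = 5L, n_classes = 2L,
                      input_length = 20L, seed = 7L,
                      recurrent_dropout = 0, recurrent_input_dropout = 0,
                      dropout_after_pool = 0, dropout_after_recurrent = 0,
                      dropout_after_dense = 0)
  m <- build_model(cfg)
  B <- 3L
  codes <- matrix(sample(1:4, B * 20, replace = TRUE), B, 20)
  Xb <- enhancerkit:::codes_to_batch(codes)
  Y <- matrix(rbinom(B * 2, 1, 0.5), B, 2)
  loss_fn <- function(params) {
    cf <- enhancerkit:::conv_forward(params, cfg, Xb)
    hf <- enhancerkit:::head_forward(params, cfg, cf$A1, cf$B, train = FALSE)
    p <- pmin(pmax(hf$out, 1e-7), 1 - 1e-7)
    -mean(Y * log(p) + (1 - Y) * log(1 - p))
  }
  res <- enhancerkit:::batch_grads(m$params, cfg, Xb, Y, train = FALSE)
  eps <- 1e-6
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    idx <- sample(length(p), min(10, length(p)))
    for (i in idx) {
      pp <- m$params; pp[[nm]][i] <- p[i] + eps; l1 <- loss_fn(pp)
      pp[[nm]][i] <- p[i] - eps; l2 <- loss_fn(pp)
      num <- (l1 - l2) / (2 * eps)
      expect_equal(res$grads[[nm]][i], num, tolerance = 1e-4,
                   info = paste("param", nm, "entry", i))
    }
  }
})

test_that("training reduces loss on a separable cohort and is seeded", {
  coh <- tiny_cohort()
  finals <- c()
  for (seed in 1:3) {
    m <- build_model(tiny_config(seed = seed), class_names = coh$classes)
    m <- train_model(m, coh$sequences, coh$label_matrix, epochs = 3L)
    expect_equal(nrow(m$log), 3L)
    finals <- rbind(finals, m$log$loss)
  }
  expect_lt(mean(finals[, 3]), mean(finals[, 1]))
  # identical seed, identical parameters
  m1 <- build_model(tiny_config(), class_names = coh$classes)
  m1 <- train_model(m1, coh$sequences, coh$label_matrix, epochs = 1L)
  m2 <- build_model(tiny_config(), class_names = coh$classes)
  m2 <- train_model(m2, coh$sequences, coh$label_matrix, epochs = 1L)
  expect_identical(m1$params, m2$params)
})

test_that("zero epochs leave parameters untouched", {
  coh <- tiny_cohort()
  m <- build_model(tiny_config(), class_names = coh$classes)
  m0 <- train_model(m, coh$sequences, coh$label_matrix, epochs = 0L)
  expect_identical(m0$params, m$params)
})

test_that("training rejects mismatched or non-binary labels", {
  coh <- tiny_cohort()
  m <- build_model(tiny_config(), class_names = coh$classes)
  bad <- coh$label_matrix
  bad[1, 1] <- 0.5
  expect_error(train_model(m, coh$sequences, bad), "binary")
  expect_error(train_model(m, coh$sequences, coh$label_matrix[-1, ]),
               "matching")
})

test_that("evaluation splits by chromosome and reports NA when undefined", {
  m <- tiny_model()
  coh <- tiny_cohort()
  ev <- evaluate_model(m, coh$sequences, coh$label_matrix,
                       coh$regions$chrom, "chr2")
  expect_setequal(unique(ev$split), c("train", "test", "shuffled"))
  expect_true(all(ev$auroc >= 0 & ev$auroc <= 1, na.rm = TRUE))
  expect_error(evaluate_model(m, coh$sequences, coh$label_matrix,
                              coh$regions$chrom, "chr99"), "heldout")
  # a labels column with no positives in the held-out chromosome
  y <- coh$label_matrix
  y[coh$regions$chrom == "chr2", 1] <- 0L
  ev2 <- evaluate_model(m, coh$sequences, y, coh$regions$chrom, "chr2")
  expect_true(is.na(ev2$auroc[ev2$split == "test" & ev2$class == "MEL"]))
})

test_that("class calls use a strict threshold", {
  regions <- region_tbl("chr1", c(0, 100, 200), c(50, 150, 250),
                        name = c("a", "b", "c"))
  scores <- matrix(c(0.16, 0.5, 0.01), 3, 1,
                   dimnames = list(NULL, "MEL"))
  called <- call_class(regions, scores, "MEL", threshold = 0.16)
  expect_equal(called$name, "b")
  expect_equal(nrow(call_class(regions, scores, "MEL", threshold = 0)), 3L)
})

test_that("threshold sweeps report recall and FDR against truth", {
  scores <- c(0.9, 0.8, 0.3, 0.2)
  labels <- c(1, 1, 0, 0)
  sw <- threshold_sweep(scores, labels, thresholds = c(0.5, 0.85))
  expect_equal(sw$recall, c(1, 0.5))
  expect_equal(sw$fdr, c(0, 0))
  expect_equal(sw$youden[1], 1)
})

test_that("model checkpoints round-trip through JSON exactly", {
  m <- tiny_model()
  p <- withr::local_tempfile(fileext = ".json")
  write_model(m, p)
  m2 <- read_model(p)
  x <- random_dna(4, 200, seed = 9)
  expect_equal(rc_averaged_predict(m, x), rc_averaged_predict(m2, x),
               tolerance = 1e-12)
  expect_equal(m2$class_names, m$class_names)
  expect_true(m2$trained)
})

test_that("tidy and glance summarize a fitted model", {
  m <- tiny_model()
  lg <- tidy(m)
  expect_true(all(c("epoch", "loss") %in% names(lg)))
  gl <- glance(m)
  expect_equal(gl$n_parameters, n_parameters(m))
  expect_true(gl$trained)
})
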