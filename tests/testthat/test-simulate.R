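test_that("a motif-free recipe yields no truth hits", {
  spec <- class_spec(1L, "BG", motifs = NULL, n_regions = 10L,
                     region_length = 100L)
  coh <- simulate_regions(spec, seed = 1L)
  expect_equal(nrow(coh$truth_hits), 0L)
  expect_true(all(nchar(coh$sequences) == 100L))
})

test_that("generation is byte-for-byte deterministic given the seed", {
  spec <- class_spec(1L, "MEL",
                     motifs = tibble::tibble(motif = "SOX_dimer", count = 1),
                     n_regions = 15L, region_length = 120L)
  a <- simulate_regions(spec, seed = 77L)
  b <- simulate_regions(spec, seed = 77L)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth_hits, b$truth_hits)
  expect_identical(a$topic_probs, b$topic_probs)
  c <- simulate_regions(spec, seed = 78L)
  expect_false(identical(a$sequences, c$sequences))
})

test_that("near-deterministic implants are recoverable by substring scan", {
  lib <- dplyr::bind_rows(motif_model("EBOX", consensus = "CACGTG", p = 0.999),
                          motif_library())
  spec <- class_spec(1L, "E",
                     motifs = tibble::tibble(motif = "EBOX", count = 1),
                     n_regions = 1000L, region_length = 60L)
  coh <- simulate_regions(spec, seed = 5L, motifs = lib)
  found <- vapply(coh$sequences, function(s) {
    grepl("CACGTG", s, fixed = TRUE) ||
      grepl("CACGTG", reverse_complement(s), fixed = TRUE)
  }, logical(1))
  expect_gte(sum(found), 990L)
  # every truth hit lies inside its region and matches the recorded span
  expect_true(all(coh$truth_hits$start >= 0))
  expect_true(all(coh$truth_hits$end <= 60))
})

test_that("motifs wider than the region are rejected with a message", {
  spec <- class_spec(1L, "X",
                     motifs = tibble::tibble(motif = "SOX_dimer", count = 1),
                     n_regions = 2L, region_length = 30L)
  expect_error(simulate_regions(spec, seed = 1L), "too wide")
})

test_that("zero-length branches leave sequences untouched", {
  coh <- tiny_cohort()
  ev <- evolve_cohort(coh, "(A:0,B:0);", seed = 3L)
  expect_identical(unname(ev$sequences$A), unname(coh$sequences))
  expect_identical(unname(ev$sequences$B), unname(coh$sequences))
  expect_true(all(ev$truth_hits$intact))
})

test_that("saturated branches preserve motifs but randomize background", {
  spec <- class_spec(1L, "MEL",
                     motifs = tibble::tibble(motif = "SOX_dimer", count = 1),
                     n_regions = 20L, region_length = 150L)
  coh <- simulate_regions(spec, seed = 10L)
  ev <- evolve_cohort(coh, "(A:100,B:100);", conserve_motifs = TRUE,
                      motif_loss_rate = 0, seed = 4L)
  anc_codes <- lapply(coh$sequences, enhancerkit:::encode_sequence)
  ident_in <- c(); ident_out <- c()
  for (r in names(coh$sequences)) {
    leaf <- enhancerkit:::encode_sequence(ev$sequences$A[[r]])
    hits <- coh$truth_hits[coh$truth_hits$region == r, ]
    inside <- unlist(mapply(function(s, e) (s + 1):e, hits$start, hits$end,
                            SIMPLIFY = FALSE))
    outside <- setdiff(seq_along(leaf), inside)
    ident_in <- c(ident_in, mean(leaf[inside] == anc_codes[[r]][inside]))
    ident_out <- c(ident_out, mean(leaf[outside] == anc_codes[[r]][outside]))
  }
  expect_equal(mean(ident_in), 1)
  expect_lt(abs(mean(ident_out) - 0.25), 0.05)
})

test_that("forced motif loss removes every intact instance", {
  spec <- class_spec(1L, "MEL",
                     motifs = tibble::tibble(motif = "MITF_ebox", count = 2,
                                             window_start = 20L,
                                             window_end = 80L),
                     n_regions = 10L, region_length = 100L)
  coh <- simulate_regions(spec, seed = 2L)
  ev <- evolve_cohort(coh, "(A:0.1,B:0.1);", motif_loss_rate = 1, seed = 6L)
  expect_true(all(!ev$truth_hits$intact[ev$truth_hits$species == "A"]))
})

test_that("negative rates are rejected", {
  coh <- tiny_cohort()
  expect_error(evolve_cohort(coh, "(A:1,B:1);", motif_loss_rate = -0.1),
               "nonnegative")
})

test_that("sequence identity to the ancestor decays with branch length", {
  spec <- class_spec(1L, "BG", motifs = NULL, n_regions = 20L,
                     region_length = 150L)
  coh <- simulate_regions(spec, seed = 30L)
  lens <- c(0.05, 0.2, 0.5, 1.5)
  mean_ident <- vapply(seq_along(lens), function(i) {
    ev <- evolve_cohort(coh, sprintf("(A:%f,B:%f);", lens[i], lens[i]),
                        conserve_motifs = FALSE, seed = 50L + i)
    mean(vapply(names(coh$sequences), function(r) {
      a <- enhancerkit:::encode_sequence(ev$sequences$A[[r]])
      b <- enhancerkit:::encode_sequence(coh$sequences[[r]])
      mean(a == b)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ident) < 0))
})

test_that("indels stay out of motifs and truth hits are remapped", {
  spec <- class_spec(1L, "MEL",
                     motifs = tibble::tibble(motif = "SOX_dimer", count = 1,
                                             window_start = 60L,
                                             window_end = 100L),
                     n_regions = 20L, region_length = 160L)
  coh <- simulate_regions(spec, seed = 12L)
  ev <- evolve_cohort(coh, "(A:0.05,B:0.05);", conserve_motifs = TRUE,
                      indel_rate = 0.02, seed = 9L)
  th <- ev$truth_hits[ev$truth_hits$species == "A", ]
  anc <- coh$truth_hits
  for (i in seq_len(nrow(th))) {
    leaf_frag <- substr(ev$sequences$A[[th$region[i]]],
                        th$start[i] + 1, th$end[i])
    a <- anc[anc$region == th$region[i], ]
    anc_frag <- substr(coh$sequences[[th$region[i]]], a$start + 1, a$end)
    # conserved instances are identical to the ancestor at the remapped
    # coordinates
    expect_identical(leaf_frag, anc_frag, label = th$region[i])
  }
})

test_that("fragment simulation conserves counts and coverage mass", {
  r <- region_tbl("chr1", 1000, 1500)
  expect_error(simulate_fragments(r, depth = 0), "depth")
  sim <- simulate_fragments(r, depth = 100, seed = 8L)
  expect_equal(nrow(sim$fragments), 100L)
  overlaps <- sim$fragments$start < 1500 & sim$fragments$end > 1000
  expect_true(all(overlaps))
  mass <- sum(sim$coverage$value * (sim$coverage$end - sim$coverage$start))
  expect_equal(mass, sum(sim$fragments$end - sim$fragments$start))
  empty <- simulate_fragments(r[0, ], depth = 10, seed = 1L)
  expect_equal(nrow(empty$fragments), 0L)
})

test_that("the activity model is negative on motif-free sequence", {
  bg <- strrep("AC", 100)
  expect_lte(activity_model(bg), 0)
})

test_that("destroying an E-box strictly decreases activity", {
  lib <- motif_library()
  cons <- lib$consensus[lib$name == "MITF_ebox"]   # TCACGTGA
  s <- paste0(strrep("AC", 40), cons, strrep("CA", 40))
  broken <- sub("CACGTG", "CAAATG", s)
  expect_lt(activity_model(broken), activity_model(s))
})

test_that("activity drops track PWM log-odds drops for a lone motif", {
  ebox <- motif_model("EBOX", consensus = "TCACGTGA", p = 0.97)
  s <- paste0(strrep("A", 10), "TCACGTGA", strrep("A", 10))
  wt_act <- activity_model(s, motifs = ebox)
  wt_lo <- best_pwm_score(s, ebox$pwm[[1]])
  chars <- strsplit(s, "")[[1]]
  act_drop <- c(); lo_drop <- c()
  for (p in seq_along(chars)) {
    for (alt in setdiff(c("A", "C", "G", "T"), chars[p])) {
      mut <- chars; mut[p] <- alt
      ms <- paste(mut, collapse = "")
      act_drop <- c(act_drop, wt_act - activity_model(ms, motifs = ebox))
      lo_drop <- c(lo_drop, wt_lo - best_pwm_score(ms, ebox$pwm[[1]]))
    }
  }
  expect_equal(cor(act_drop, lo_drop, method = "spearman"), 1, tolerance = 1e-9)
})

test_that("cohorts and evolved cohorts write standard formats", {
  coh <- tiny_cohort()
  dir <- withr::local_tempdir()
  files <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "sequences.fa")))
  fa <- read_fasta(file.path(dir, "sequences.fa"))
  expect_identical(unname(fa), unname(coh$sequences))
  tr <- read_bed(file.path(dir, "truth_hits.bed"))
  expect_equal(nrow(tr), nrow(coh$truth_hits))
  ev <- evolve_cohort(coh, "(A:0.1,B:0.2);", seed = 2L)
  files2 <- write_cohort(ev, file.path(dir, "ev"))
  expect_true(file.exists(file.path(dir, "ev", "A.fa")))
  expect_true(file.exists(file.path(dir, "ev", "tree.nwk")))
  tree <- ape::read.tree(file.path(dir, "ev", "tree.nwk"))
  expect_setequal(tree$tip.label, c("A", "B"))
})
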