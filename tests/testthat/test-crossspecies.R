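lib <- motif_library()
ebox <- lib$pwm[[which(lib$name == "MITF_ebox")]]

test_that("CRM scoring hits its closed-form endpoints", {
  # no position above the floor
  expect_equal(crm_score(strrep("N", 50), ebox, window_bp = 50), 0)
  # a single exact consensus in neutral (N) background scores the PWM maximum
  cons <- lib$consensus[lib$name == "MITF_ebox"]
  s <- paste0(strrep("N", 20), cons, strrep("N", 20))
  lo <- enhancerkit:::pwm_log_odds(ebox)[, 1:4]
  expect_equal(crm_score(s, ebox, window_bp = nchar(s)),
               sum(apply(lo, 1, max)), tolerance = 1e-9)
})

# independent oracle: enumerate all windows and all non-overlapping
# placement subsets recursively
crm_oracle <- function(sequence, pwm, window_bp, hit_floor = 0) {
  codes <- enhancerkit:::encode_sequence(sequence)
  W <- nrow(pwm)
  L <- length(codes)
  if (L < W) return(0)
  s <- pmax(enhancerkit:::scan_codes(codes, pwm),
            enhancerkit:::scan_codes(codes, enhancerkit:::pwm_rc(pwm)))
  best_set <- function(pos, val) {
    if (length(pos) == 0) return(0)
    # take or skip the first position
    skip <- best_set(pos[-1], val[-1])
    keep_ok <- pos >= pos[1] + W
    take <- val[1] + best_set(pos[keep_ok], val[keep_ok])
    max(skip, take)
  }
  best <- 0
  for (a in 1:(max(L - window_bp + 1, 1))) {
    b <- min(a + window_bp - W, L - W + 1)
    if (b < a) next
    idx <- a:b
    ok <- idx[s[idx] > hit_floor]
    best <- max(best, best_set(ok, s[ok]))
  }
  best
}

test_that("CRM scores agree with exhaustive placement enumeration", {
  set.seed(31)
  m <- motif_model("M4", consensus = "ACGT", p = 0.9)$pwm[[1]]
  for (rep in 1:15) {
    s <- random_dna(1, sample(20:60, 1))
    win <- sample(10:30, 1)
    expect_equal(crm_score(s, m, window_bp = win),
                 crm_oracle(s, m, window_bp = win),
                 tolerance = 1e-9, info = s)
  }
})

test_that("prepending neutral background never lowers the CRM score", {
  set.seed(32)
  for (rep in 1:5) {
    s <- random_dna(1, 40)
    base <- crm_score(s, ebox, window_bp = 40)
    padded <- crm_score(paste0(strrep("N", 25), s), ebox, window_bp = 40)
    expect_gte(padded + 1e-9, base)
  }
})

test_that("BLS endpoints: single positive leaf and full tree", {
  tree <- ape::read.tree(text = "((A:1,B:2):0.5,(C:0.25,D:0.75):1);")
  total <- sum(tree$edge.length)
  expect_equal(bls(tree, c(A = 5, B = 0, C = 0, D = 0)), 0)
  expect_equal(bls(tree, c(A = 1, B = 1, C = 1, D = 1)), total)
  expect_equal(bls(tree, c(A = 1, B = 1, C = 0, D = 0)), 3)  # A-B subtree
  expect_error(bls(tree, c(A = 1, E = 1)), "not in tree")
})

test_that("BLS equals the path-union oracle on random trees", {
  set.seed(33)
  for (rep in 1:200) {
    n_leaf <- sample(2:8, 1)
    tree <- ape::rtree(n_leaf)
    n_pos <- sample(1:n_leaf, 1)
    pos <- sample(tree$tip.label, n_pos)
    scores <- setNames(as.numeric(tree$tip.label %in% pos), tree$tip.label)
    got <- bls(tree, scores)
    # oracle: union of edges on all pairwise tip paths
    if (n_pos <= 1) {
      expect_equal(got, 0)
      next
    }
    tips <- match(pos, tree$tip.label)
    edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
    used <- character(0)
    for (i in seq_along(tips)) {
      for (j in seq_along(tips)) {
        if (i >= j) next
        np <- ape::nodepath(tree, tips[i], tips[j])
        for (k in seq_len(length(np) - 1)) {
          used <- union(used, c(paste(np[k], np[k + 1]),
                                paste(np[k + 1], np[k])))
        }
      }
    }
    expect_equal(got, sum(tree$edge.length[edge_key %in% used]),
                 tolerance = 1e-9)
  }
})

test_that("BLS equals exhaustive edge-subset minimization on small trees", {
  set.seed(34)
  for (rep in 1:25) {
    n_leaf <- sample(3:6, 1)
    tree <- ape::rtree(n_leaf)
    pos <- sample(tree$tip.label, sample(2:n_leaf, 1))
    scores <- setNames(as.numeric(tree$tip.label %in% pos), tree$tip.label)
    ne <- nrow(tree$edge)
    best <- Inf
    tips <- match(pos, tree$tip.label)
    for (mask in 0:(2^ne - 1)) {
      sel <- which(bitwAnd(mask, 2^(0:(ne - 1))) > 0)
      # does the selected edge set connect all positive tips?
      comp <- seq_len(max(tree$edge))
      find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
      for (e in sel) {
        a <- find(tree$edge[e, 1]); b <- find(tree$edge[e, 2])
        comp[a] <- b
      }
      roots <- vapply(tips, find, integer(1))
      if (length(unique(roots)) == 1) {
        best <- min(best, sum(tree$edge.length[sel]))
      }
    }
    expect_equal(bls(tree, scores), best, tolerance = 1e-9)
  }
})

test_that("adding a positive leaf never decreases the BLS", {
  set.seed(35)
  for (rep in 1:10) {
    tree <- ape::rtree(6)
    pos <- sample(tree$tip.label, 2)
    extra <- sample(setdiff(tree$tip.label, pos), 1)
    s1 <- setNames(as.numeric(tree$tip.label %in% pos), tree$tip.label)
    s2 <- setNames(as.numeric(tree$tip.label %in% c(pos, extra)),
                   tree$tip.label)
    expect_gte(bls(tree, s2), bls(tree, s1))
  }
})

test_that("an identity shuffler zeroes every normalized BLS", {
  coh <- tiny_cohort()
  ids <- head(names(coh$sequences), 6)
  small <- coh
  small$sequences <- coh$sequences[ids]
  small$truth_hits <- coh$truth_hits[coh$truth_hits$region %in% ids, ]
  ev <- evolve_cohort(small, "((A:0.05,B:0.05):0.02,C:0.08);", seed = 3L)
  tab <- bls_table(ev$sequences, motif_library(), ev$tree,
                   shuffler = function(sequence, seed) sequence)
  expect_equal(tab$normalized_bls, rep(0, nrow(tab)))
})

test_that("shuffles preserve base composition", {
  s <- random_dna(1, 80, seed = 36)
  sh <- shuffle_sequence(s, seed = 1)
  expect_false(identical(s, sh))
  expect_equal(sort(strsplit(s, "")[[1]]), sort(strsplit(sh, "")[[1]]))
})

test_that("a conserved motif tops the normalized BLS ranking", {
  wins <- 0L
  for (seed in 1:3) {
    spec <- class_spec(1L, "S",
                       motifs = tibble::tibble(motif = "SOX_dimer", count = 2),
                       n_regions = 8L, region_length = 200L)
    coh <- simulate_regions(spec, seed = 100L + seed)
    ev <- evolve_cohort(coh, "((A:0.3,B:0.3):0.1,(C:0.3,D:0.3):0.1);",
                        conserve_motifs = TRUE, seed = seed)
    tab <- bls_table(ev$sequences, motif_library(), ev$tree,
                     window_bp = 200L, seed = seed)
    if (tab$motif[1] == "SOX_dimer") wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("global alignment matches needle-style expectations", {
  s <- "ACGTACGTAC"
  self <- global_align(s, s)
  expect_equal(self$identity, 100)
  expect_equal(nrow(self$substitutions), 0L)
  expect_equal(nrow(self$indels), 0L)
  expect_equal(self$score, 10 * 5)

  a <- global_align("ACGT", "AGT")
  expect_equal(a$identity, 75)
  expect_equal(sum(a$indels$length), 1L)
  expect_equal(a$score, 3 * 5 - 10.5)
  expect_error(global_align("", "ACGT"), "nonempty")
})

test_that("alignment scores equal brute-force enumeration on short pairs", {
  set.seed(37)
  for (rep in 1:100) {
    a <- random_dna(1, sample(2:8, 1))
    b <- random_dna(1, sample(2:8, 1))
    expect_equal(global_align(a, b)$score,
                 enhancerkit:::align_score_bruteforce(a, b),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("alignment score is invariant under joint reverse complement", {
  set.seed(38)
  for (rep in 1:10) {
    a <- random_dna(1, 30)
    b <- random_dna(1, 28)
    expect_equal(global_align(a, b)$score,
                 global_align(reverse_complement(a),
                              reverse_complement(b))$score,
                 tolerance = 1e-9)
  }
})

test_that("ortholog pairs respect the identity filter and score closure", {
  m <- tiny_model()
  coh <- tiny_cohort()
  ids <- head(names(coh$sequences), 5)
  # identical pair: identity 100, delta 0
  corr <- tibble::tibble(region_a = ids, region_b = ids)
  pairs <- build_ortholog_pairs(corr, coh$sequences[ids], coh$sequences[ids],
                                m, class_id = "MEL")
  expect_equal(nrow(pairs), 5L)
  expect_equal(pairs$identity, rep(100, 5))
  expect_equal(pairs$delta_score, rep(0, 5))
  # a heavily diverged partner fails the strict >80 filter
  div <- vapply(coh$sequences[ids], function(s) shuffle_sequence(s, seed = 1),
                character(1))
  pairs2 <- build_ortholog_pairs(corr, coh$sequences[ids],
                                 setNames(div, ids), m, class_id = "MEL")
  expect_equal(nrow(pairs2), 0L)
})

test_that("applying all point substitutions reproduces the partner score", {
  m <- tiny_model()
  coh <- tiny_cohort()
  id <- names(coh$sequences)[1]
  a <- coh$sequences[[id]]
  # substitutions only (no indels): mutate 6 scattered positions
  codes <- enhancerkit:::encode_sequence(a)
  pos <- seq(10, 160, by = 30)
  codes[pos] <- ((codes[pos]) %% 4L) + 1L
  b <- enhancerkit:::decode_codes(codes)
  pairs <- build_ortholog_pairs(tibble::tibble(region_a = id, region_b = id),
                                setNames(a, id), setNames(b, id), m,
                                class_id = "MEL")
  eff <- per_mutation_effects(pairs[1, ], a, m, class_id = "MEL")
  expect_equal(nrow(eff), length(pos))
  # closure: all substitutions together give exactly the partner's score
  sc <- rc_averaged_predict(m, c(a, b))[, "MEL"]
  full <- enhancerkit:::encode_sequence(a)
  full[eff$pos_a + 1L] <- match(eff$alt, c("A", "C", "G", "T"))
  expect_equal(unname(rc_averaged_predict(
    m, enhancerkit:::decode_codes(full))[, "MEL"]),
    unname(sc[2]), tolerance = 1e-12)
  # zero substitutions -> empty list
  p0 <- build_ortholog_pairs(tibble::tibble(region_a = id, region_b = id),
                             setNames(a, id), setNames(a, id), m, "MEL")
  expect_equal(nrow(per_mutation_effects(p0[1, ], a, m, "MEL")), 0L)
})

test_that("embedding correlations are well-defined and symmetric", {
  set.seed(39)
  E <- matrix(rnorm(5 * 12), 5, 12)
  cc <- embedding_correlation(E)
  expect_equal(diag(cc), rep(1, 5))
  expect_lt(max(abs(cc - t(cc))), 1e-12)
  E[2, ] <- 3
  expect_warning(cc2 <- embedding_correlation(E), "zero-variance")
  expect_equal(cc2[2, 3], 0)
  expect_equal(cc2[2, 2], 1)
})
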