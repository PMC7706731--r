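mk_hits <- function(region, family, center = 50, norm = 0.9) {
  tibble::tibble(region = region, filter = 1L, family = family,
                 start = as.integer(center - 10), end = as.integer(center + 10),
                 center = center, strand = ".", raw = norm, norm = norm,
                 passes_threshold = TRUE)
}

test_that("motif-hit counting matches a brute-force recount", {
  hits <- dplyr::bind_rows(
    mk_hits("r1", "SOX", 30), mk_hits("r1", "SOX", 80),
    mk_hits("r1", "MITF", 120), mk_hits("r2", "TFAP2A", 60)
  )
  counts <- count_motif_hits(hits, regions = c("r1", "r2", "r3"))
  expect_equal(counts$SOX, c(2L, 0L, 0L))
  expect_equal(counts$MITF, c(1L, 0L, 0L))
  expect_equal(counts$TFAP2A, c(0L, 1L, 0L))
  # brute force via BED round-trip
  p <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(hits, p)
  bed <- read_bed(p)
  for (fam in c("SOX", "MITF", "TFAP2A")) {
    for (r in c("r1", "r2", "r3")) {
      expect_equal(counts[[fam]][counts$region == r],
                   sum(bed$chrom == r & bed$name == fam))
    }
  }
  # empty hits -> zero matrix with the requested family columns
  z <- count_motif_hits(hits[0, ], regions = c("r1", "r2"),
                        families = c("SOX", "MITF"))
  expect_equal(z$SOX, c(0L, 0L))
  expect_equal(z$MITF, c(0L, 0L))
  # unknown family goes to 'other' with a warning
  h2 <- mk_hits("r1", NA_character_)
  expect_warning(c2 <- count_motif_hits(h2, regions = "r1"), "other")
  expect_equal(c2$other, 1L)
})

test_that("full-factorial compositions with an anchor family give 8 classes", {
  combos <- expand.grid(TFAP2A = 0:1, MITF = 0:1, RUNX = 0:1)
  counts <- tibble::tibble(
    region = paste0("r", seq_len(2 * nrow(combos))),
    SOX = rep(c(1L, 2L), nrow(combos)),
    TFAP2A = rep(combos$TFAP2A, each = 2),
    MITF = rep(combos$MITF, each = 2),
    RUNX = rep(combos$RUNX, each = 2)
  )
  comp <- classify_composition(counts, require_family = "SOX")
  expect_equal(nrow(comp$inventory), 8L)
  expect_true(all(comp$assignments$conforming))
  expect_true(all(grepl("SOX", comp$assignments$class)))
})

test_that("composition classes collapse and bucket as specified", {
  counts <- tibble::tibble(region = c("a", "b", "c"),
                           SOX = c(1L, 1L, 0L), MITF = c(2L, 5L, 1L))
  comp <- classify_composition(counts)
  expect_equal(length(unique(comp$assignments$class[1:2])), 1L)
  comp2 <- classify_composition(counts, require_family = "SOX")
  expect_false(comp2$assignments$conforming[3])
  expect_equal(sum(comp2$inventory$n), 3L)  # nothing silently dropped
})

test_that("composition clustering is idempotent and order-independent", {
  set.seed(41)
  counts <- tibble::tibble(region = paste0("r", 1:30),
                           A = rpois(30, 1), B = rpois(30, 1),
                           C = rpois(30, 0.5))
  c1 <- classify_composition(counts)
  perm <- sample(30)
  c2 <- classify_composition(counts[perm, ])
  expect_equal(dplyr::arrange(c1$inventory, class),
               dplyr::arrange(c2$inventory, class))
  expect_equal(c1$assignments$class[perm], c2$assignments$class)
})

test_that("signal aggregation reproduces a shared local track", {
  # same triangular bump around every anchor
  bump <- c(1:10, 9:1)
  track <- dplyr::bind_rows(lapply(c("r1", "r2"), function(r) {
    tibble::tibble(chrom = r, start = 41:59, end = 42:60, value = bump)
  }))
  anchors <- region_tbl(c("r1", "r2"), c(40, 40), c(61, 61))
  prof <- aggregate_signal(track, anchors, flank_bp = 9)
  expect_equal(prof$mean, bump, tolerance = 1e-12)
  expect_equal(prof$n[1], 2L)
})

test_that("shifting anchors shifts the aggregate the other way", {
  set.seed(42)
  v <- runif(200)
  track <- tibble::tibble(chrom = "r1", start = 0:199, end = 1:200, value = v)
  a1 <- region_tbl("r1", 90, 111)   # summit 100
  a2 <- region_tbl("r1", 97, 118)   # summit 107
  p1 <- aggregate_signal(track, a1, flank_bp = 20)
  p2 <- aggregate_signal(track, a2, flank_bp = 20)
  expect_equal(p1$mean[(1 + 7):(41)], p2$mean[1:(41 - 7)], tolerance = 1e-12)
})

test_that("a bump planted at a fixed offset from motifs is recovered", {
  set.seed(43)
  offset_truth <- 15L
  rows <- list(); anchors <- list()
  for (i in 1:20) {
    center <- sample(60:140, 1)
    strand <- sample(c("+", "-"), 1)
    v <- rep(0.1, 200)
    pos <- if (strand == "+") center + offset_truth else center - offset_truth
    v[pos + 1] <- 5
    rows[[i]] <- tibble::tibble(chrom = paste0("r", i), start = 0:199,
                                end = 1:200, value = v)
    anchors[[i]] <- tibble::tibble(region = paste0("r", i), center = center,
                                   strand = strand)
  }
  prof <- aggregate_signal(dplyr::bind_rows(rows),
                           dplyr::bind_rows(anchors), flank_bp = 40)
  expect_equal(prof$offset[which.max(prof$mean)], offset_truth)
})

test_that("anchors too close to the track edge are excluded and counted", {
  track <- tibble::tibble(chrom = "r1", start = 0:99, end = 1:100, value = 1)
  anchors <- region_tbl(c("r1", "r1"), c(0, 40), c(10, 60))
  prof <- aggregate_signal(track, anchors, flank_bp = 30)
  expect_equal(prof$n[1], 1L)
  expect_equal(attr(prof, "excluded"), 1L)
})

test_that("Tn5 cut profiles count fragment ends with linearity", {
  frag <- tibble::tibble(chrom = "r1", start = 100L, end = 150L, strand = "+")
  anchors <- tibble::tibble(region = "r1", center = 100L, strand = ".")
  prof <- tn5_cut_profile(frag, anchors, flank_bp = 60)
  expect_equal(prof$count[prof$offset == 0], 1)
  expect_equal(prof$count[prof$offset == 49], 1)
  expect_equal(sum(prof$count), 2)
  # doubling fragments doubles the profile
  prof2 <- tn5_cut_profile(dplyr::bind_rows(frag, frag), anchors, 60)
  expect_equal(prof2$count, 2 * prof$count)
  # offset correction moves the plus-strand cut by +4
  prof3 <- tn5_cut_profile(frag, anchors, 60, offset_correct = TRUE)
  expect_equal(prof3$count[prof3$offset == 4], 1)
})

test_that("bedGraph tracks round-trip", {
  track <- tibble::tibble(chrom = c("r1", "r1"), start = c(0L, 10L),
                          end = c(10L, 25L), value = c(1.5, 0.25))
  p <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(track, p)
  expect_equal(as.data.frame(read_bedgraph(p)), as.data.frame(track))
})
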