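#' Construct a motif model
#'
#' A motif model couples a position weight matrix (PWM; W x 4 base
#' probabilities in A, C, G, T order, rows summing to 1) with a name,
#' a family label and its consensus string (per-position argmax base).
#'
#' @param name Motif name.
#' @param pwm W x 4 probability matrix; alternatively supply `consensus`.
#' @param consensus Consensus string used to build a near-deterministic PWM
#'   when `pwm` is not given. Besides A/C/G/T, `N` (uniform) and `S` (C or
#'   G) are understood.
#' @param family Motif family label (defaults to `name`).
#' @param p Probability mass on the consensus base when building from a
#'   consensus string (default 0.97, near-deterministic).
#' @return A one-row tibble with columns `name`, `family`, `width`,
#'   `consensus` and a `pwm` list-column.
#' @export
motif_model <- function(name, pwm = NULL, consensus = NULL, family = name,
                        p = 0.97) {
  if (is.null(pwm)) {
    assert_that(!is.null(consensus), "supply `pwm` or `consensus`")
    pwm <- pwm_from_consensus(consensus, p = p)
  }
  pwm <- validate_pwm(pwm)
  tibble(
    name = name,
    family = family,
    width = nrow(pwm),
    consensus = pwm_consensus(pwm),
    pwm = list(pwm)
  )
}

validate_pwm <- function(pwm) {
  pwm <- as.matrix(pwm)
  assert_that(ncol(pwm) == 4L, "PWM must have 4 columns (A,C,G,T)")
  assert_that(nrow(pwm) >= 4L, "PWM width must be >= 4")
  assert_that(all(pwm >= 0 & pwm <= 1), "PWM entries must lie in [0,1]")
  assert_that(max(abs(rowSums(pwm) - 1)) < 1e-9, "PWM rows must sum to 1")
  colnames(pwm) <- DNA_BASES
  pwm
}

pwm_from_consensus <- function(consensus, p = 0.97) {
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  rows <- lapply(chars, function(ch) {
    if (ch == "N") return(rep(0.25, 4))
    if (ch == "S") return(c(0.015, 0.485, 0.485, 0.015))
    if (ch == "W") return(c(0.485, 0.015, 0.015, 0.485))
    i <- match(ch, DNA_BASES)
    assert_that(!is.na(i), paste0("unsupported consensus character: ", ch))
    row <- rep((1 - p) / 3, 4)
    row[i] <- p
    row
  })
  do.call(rbind, rows)
}

#' Consensus string of a PWM
#'
#' Per-position argmax base (ties resolved in A, C, G, T order).
#'
#' @param pwm A W x 4 probability matrix.
#' @return A character string of length W.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[max.col(pwm, ties.method = "first")], collapse = "")
}

#' Per-column information content of a PWM
#'
#' @param pwm A W x 4 probability matrix.
#' @return Numeric vector of length W (bits, in `[0, 2]`).
#' @export
pwm_ic <- function(pwm) {
  p <- pmax(pwm, 1e-12)
  2 + rowSums(p * log2(p))
}

# Reverse complement of a PWM.
pwm_rc <- function(pwm) {
  out <- pwm[rev(seq_len(nrow(pwm))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- DNA_BASES
  out
}

# Log-odds matrix against a uniform 0.25 background, with a pseudo-frequency
# guard for zero counts. Column 5 holds the N score (0 = uninformative).
pwm_log_odds <- function(pwm, pseudo = 1e-3) {
  lo <- cbind(log2((pwm + pseudo) / (0.25 + pseudo)), 0)
  dimnames(lo) <- NULL
  lo
}

#' Scan a sequence with a PWM
#'
#' Computes per-position log-odds scores (uniform 0.25 background) on both
#' strands. Position `i` (1-based) covers `[i, i + W)`; `N` bases
#' contribute a score of 0.
#'
#' @param sequence A DNA string.
#' @param pwm A W x 4 probability matrix.
#' @return A tibble with `pos` (1-based), `fwd`, `rev`, `best` (max of the
#'   two strands) and `strand` of the best hit.
#' @export
scan_pwm <- function(sequence, pwm) {
  codes <- encode_sequence(sequence)
  W <- nrow(pwm)
  L <- length(codes)
  if (L < W) {
    return(tibble(pos = integer(), fwd = numeric(), rev = numeric(),
                  best = numeric(), strand = character()))
  }
  fwd <- scan_codes(codes, pwm)
  rev_ <- scan_codes(codes, pwm_rc(pwm))
  tibble(
    pos = seq_len(L - W + 1L),
    fwd = fwd,
    rev = rev_,
    best = pmax(fwd, rev_),
    strand = ifelse(fwd >= rev_, "+", "-")
  )
}

scan_codes <- function(codes, pwm) {
  W <- nrow(pwm)
  L <- length(codes)
  lo <- pwm_log_odds(pwm)
  idx <- ifelse(codes == 0L, 5L, codes)
  n_pos <- L - W + 1L
  score <- numeric(n_pos)
  for (k in seq_len(W)) {
    score <- score + lo[k, idx[k:(k + n_pos - 1L)]]
  }
  score
}

#' Best PWM match score in a sequence
#'
#' @inheritParams scan_pwm
#' @return The maximum best-strand log-odds score (or `-Inf` for sequences
#'   shorter than the motif).
#' @export
best_pwm_score <- function(sequence, pwm) {
  sc <- scan_pwm(sequence, pwm)
  if (nrow(sc) == 0) return(-Inf)
  max(sc$best)
}

#' Default synthetic motif library
#'
#' Seven near-deterministic PWMs standing in for the core melanoma motif
#' families: a SOX dimer (two `AACAAT` half-sites in inverted orientation),
#' an E-box (MITF-like, `CACGTG` core), TFAP2A-like (`GCC..GGC`),
#' RUNX-like (`TGTGGT` core), AP-1 (`TGASTCA`), TEAD (`GGAATG`) and a
#' GC-rich promoter motif (SP-like). These drive the synthetic class
#' recipes and serve as ground truth for motif-recovery tests.
#'
#' @param p Consensus-base probability (default 0.97, near-deterministic).
#' @return A motif library tibble (one row per motif; `pwm` list-column).
#' @export
motif_library <- function(p = 0.97) {
  dplyr::bind_rows(
    motif_model("SOX_dimer", consensus = "AACAATGGCATTGTT", family = "SOX", p = p),
    motif_model("MITF_ebox", consensus = "TCACGTGA", family = "MITF", p = p),
    motif_model("TFAP2A", consensus = "GCCTSAGGC", family = "TFAP2A", p = p),
    motif_model("RUNX", consensus = "CTGTGGTTT", family = "RUNX", p = p),
    motif_model("AP1", consensus = "TGASTCA", family = "AP1", p = p),
    motif_model("TEAD", consensus = "GGAATGC", family = "TEAD", p = p),
    motif_model("SP_GC", consensus = "GGGGCGGGG", family = "SP", p = p)
  )
}

#' Write / read PWMs in JASPAR-style tab format
#'
#' One block per motif: a `>name` header followed by four rows
#' (`A [ ... ]` etc.) of probabilities.
#'
#' @param motifs A motif library tibble.
#' @param path Output path.
#' @export
write_pwm_jaspar <- function(motifs, path) {
  lines <- unlist(lapply(seq_len(nrow(motifs)), function(i) {
    pwm <- motifs$pwm[[i]]
    c(paste0(">", motifs$name[i]),
      vapply(1:4, function(j) {
        paste0(DNA_BASES[j], " [ ",
               paste(formatC(pwm[, j], format = "f", digits = 6), collapse = " "),
               " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pwm_jaspar
#' @return `read_pwm_jaspar()` returns a motif library tibble.
#' @export
read_pwm_jaspar <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  out <- lapply(seq_along(heads), function(i) {
    nm <- sub("^>\\s*", "", lines[heads[i]])
    block <- lines[(heads[i] + 1):(heads[i] + 4)]
    rows <- lapply(block, function(l) {
      as.numeric(strsplit(gsub("^[ACGT]\\s*\\[\\s*|\\s*\\]\\s*$", "", l),
                          "\\s+")[[1]])
    })
    pwm <- do.call(cbind, rows)
    pwm <- pwm / rowSums(pwm)
    motif_model(nm, pwm = pwm)
  })
  dplyr::bind_rows(out)
}

#' Write / read PWMs in Cluster-Buster-style text format
#'
#' One block per motif: a `>name` header followed by W rows of four counts
#' (A C G T).
#'
#' @param motifs A motif library tibble.
#' @param path Output path.
#' @param scale Count scale per row (default 100).
#' @export
write_pwm_clusterbuster <- function(motifs, path, scale = 100) {
  lines <- unlist(lapply(seq_len(nrow(motifs)), function(i) {
    pwm <- motifs$pwm[[i]]
    c(paste0(">", motifs$name[i]),
      apply(round(pwm * scale, 3), 1, paste, collapse = "\t"))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pwm_clusterbuster
#' @return `read_pwm_clusterbuster()` returns a motif library tibble.
#' @export
read_pwm_clusterbuster <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  bounds <- c(heads, length(lines) + 1L)
  out <- lapply(seq_along(heads), function(i) {
    nm <- sub("^>\\s*", "", lines[heads[i]])
    block <- lines[(heads[i] + 1):(bounds[i + 1] - 1)]
    pwm <- do.call(rbind, lapply(block, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    pwm <- pwm / rowSums(pwm)
    motif_model(nm, pwm = pwm)
  })
  dplyr::bind_rows(out)
}
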