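#' One-hot encode a DNA sequence
#'
#' Encodes an `ACGTN` string (case-insensitive) as an L x 4 matrix with
#' columns in A, C, G, T order. Standard bases give a single 1 per row;
#' `N` gives an all-zero row so the model sees no signal at ambiguous
#' positions. Any other character is an error.
#'
#' @param sequence A single character string.
#' @return An L x 4 numeric matrix with colnames `A,C,G,T`.
#' @examples
#' one_hot("ACGT")
#' @export
one_hot <- function(sequence) {
  codes <- encode_sequence(sequence)
  m <- matrix(0, length(codes), 4L, dimnames = list(NULL, DNA_BASES))
  hit <- which(codes > 0L)
  m[cbind(hit, codes[hit])] <- 1
  m
}

#' Decode a one-hot matrix back to a sequence string
#'
#' Inverse of [one_hot()]; all-zero rows decode to `N`.
#'
#' @param mat An L x 4 one-hot matrix.
#' @return A character string.
#' @export
one_hot_decode <- function(mat) {
  assert_that(is.matrix(mat) && ncol(mat) == 4L, "`mat` must be an L x 4 matrix")
  idx <- max.col(mat, ties.method = "first")
  idx[rowSums(mat) == 0] <- NA_integer_
  paste(ifelse(is.na(idx), "N", DNA_BASES[idx]), collapse = "")
}

#' Reverse complement
#'
#' For a string, returns the reverse-complemented string (`N` maps to `N`).
#' For a one-hot matrix, reverses the row order and swaps the A/T and C/G
#' columns, so that `reverse_complement(one_hot(s))` equals
#' `one_hot(reverse_complement(s))`.
#'
#' @param x A character vector of sequences or a one-hot matrix.
#' @return Same type as the input.
#' @export
reverse_complement <- function(x) {
  if (is.matrix(x)) {
    out <- x[rev(seq_len(nrow(x))), c(4L, 3L, 2L, 1L), drop = FALSE]
    colnames(out) <- DNA_BASES
    return(out)
  }
  vapply(x, function(s) {
    codes <- encode_sequence(s)
    rc <- rev(ifelse(codes == 0L, 0L, 5L - codes))
    decode_codes(rc)
  }, character(1), USE.NAMES = FALSE)
}

# Integer codes: A=1, C=2, G=3, T=4, N=0. The model's batched input is kept
# in this compact form and expanded to one-hot per minibatch.
encode_sequence <- function(sequence) {
  assert_that(is.character(sequence) && length(sequence) == 1L,
              "`sequence` must be a single string")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  codes <- match(chars, c(DNA_BASES, "N"))
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    abort(paste0("sequence contains non-ACGTN characters: ",
                 paste(bad, collapse = ", ")))
  }
  codes[codes == 5L] <- 0L
  codes
}

decode_codes <- function(codes) {
  paste(ifelse(codes == 0L, "N", DNA_BASES[pmax(codes, 1L)]), collapse = "")
}

# Encode many sequences of equal length L into an N x L integer matrix.
encode_matrix <- function(sequences) {
  L <- unique(nchar(sequences))
  assert_that(length(L) == 1L, "all sequences must have equal length")
  t(vapply(sequences, encode_sequence, integer(L), USE.NAMES = FALSE))
}

# Reverse complement of an integer code matrix (N x L).
rc_codes <- function(codes) {
  out <- codes[, rev(seq_len(ncol(codes))), drop = FALSE]
  nz <- out != 0L
  out[nz] <- 5L - out[nz]
  out
}

# Expand an N x L code matrix into the batch layout used by the network:
# an N x (4L) matrix, position-major (pos1:A,C,G,T, pos2:A,C,G,T, ...).
codes_to_batch <- function(codes) {
  n <- nrow(codes)
  L <- ncol(codes)
  X <- matrix(0, n, 4L * L)
  pos <- rep(seq_len(L), each = n)
  row <- rep(seq_len(n), times = L)
  code <- as.vector(codes)
  keep <- code > 0L
  X[cbind(row[keep], 4L * (pos[keep] - 1L) + code[keep])] <- 1
  X
}
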