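#' @useDynLib enhancerkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map2 pmap imap
#' @importFrom stats rnorm runif rpois rbinom cor sd quantile setNames
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child seed from a master seed
#'
#' All randomness in the package funnels through integer seeds; stage-level
#' seeds are derived deterministically from a master seed so that a single
#' `--seed` reproduces a whole pipeline. Kept below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stage Stage label (character) or integer offset.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  as.integer((as.numeric(seed) * 48271 + as.numeric(stage) * 16807) %% 2147483629L)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
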