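#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_point geom_tile
#'   facet_wrap labs theme_minimal scale_fill_manual scale_color_manual
#'   autoplot geom_hline
NULL

#' @export
ggplot2::autoplot

base_fill <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")

#' @export
autoplot.aggregate_profile <- function(object, ...) {
  ycol <- if ("mean" %in% names(object)) "mean" else "count"
  ggplot(object, aes(x = .data$offset, y = .data[[ycol]])) +
    geom_line(color = "#255C99") +
    labs(x = "offset from anchor (bp)", y = ycol,
         title = paste0("aggregate profile (n = ", object$n[1], ")")) +
    theme_minimal()
}

#' @export
autoplot.enhancer_eval <- function(object, metric = "auroc", ...) {
  ggplot(object, aes(x = .data$class, y = .data[[metric]],
                     fill = .data$split)) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = 0.5, linetype = "dashed", color = "grey50") +
    labs(x = NULL, y = metric) +
    theme_minimal()
}

#' Plot an attribution profile as per-base contribution bars
#'
#' Observed-base contributions are drawn as bars coloured by base, the
#' standard compact alternative to a sequence logo.
#'
#' @param profile An `attribution_profile`.
#' @param from,to Optional 1-based position window to display.
#' @return A ggplot object.
#' @export
plot_attribution <- function(profile, from = 1L, to = NULL) {
  L <- nrow(profile$observed)
  to <- to %||% L
  pos <- from:to
  base <- strsplit(toupper(profile$sequence), "")[[1]][pos]
  df <- tibble(position = pos, base = base,
               contribution = profile$position[pos])
  ggplot(df, aes(x = .data$position, y = .data$contribution,
                 fill = .data$base)) +
    geom_col(width = 1) +
    scale_fill_manual(values = base_fill, na.value = "grey70") +
    labs(x = "position (bp)", y = "contribution",
         title = paste0("attribution, class ", profile$class_id,
                        " (residual ", signif(profile$residual, 2), ")")) +
    theme_minimal()
}

#' @export
autoplot.mutagenesis_map <- function(object, class = 1L, ...) {
  df <- tidy(object)
  cls <- if (is.numeric(class)) object$class_names[class] else class
  df <- df[df$class == cls, ]
  ggplot(df, aes(x = .data$position, y = .data$delta, color = .data$alt)) +
    geom_point(size = 0.6) +
    scale_color_manual(values = base_fill) +
    labs(x = "position (bp)", y = "delta score",
         title = paste0("in silico saturation mutagenesis, class ", cls)) +
    theme_minimal()
}

#' @export
autoplot.bls_table <- function(object, ...) {
  df <- as_tibble(object)
  df$motif <- factor(df$motif, levels = rev(df$motif[order(df$rank)]))
  ggplot(df, aes(x = .data$normalized_bls, y = .data$motif)) +
    geom_col(fill = "#255C99") +
    labs(x = "normalized branch length score", y = NULL) +
    theme_minimal()
}
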