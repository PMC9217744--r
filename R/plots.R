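#' Heatmap of an aggregate Repli-seq profile
#'
#' Fractions (earliest at the top) by genomic position around the boundary,
#' the standard presentation of boundary-centered 16-fraction Repli-seq.
#'
#' @param object An `aggregate_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aggregate_profile <- function(object, ...) {
  k <- object$flank_bins
  df <- tidyr::expand_grid(fraction = 1:16, offset = -k:k)
  df$signal <- as.vector(t(object$mat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$fraction,
                                   fill = .data$signal)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = c(1, 8, 16)) +
    ggplot2::scale_fill_viridis_c(name = "signal") +
    ggplot2::labs(x = "offset from boundary (bins)", y = "S-phase fraction",
                  subtitle = paste0("n = ", object$n)) +
    ggplot2::theme_minimal()
}

#' Observed versus null colocalization counts
#'
#' One panel per (boundary class, timing class) cell: the null count
#' distribution with the observed count as a vertical line.
#'
#' @param object An `iz_enrichment` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.iz_enrichment <- function(object, ...) {
  tab <- object$table
  nulls <- purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    tibble::tibble(class_index = tab$class_index[i],
                   timing_class = tab$timing_class[i],
                   count = object$null_counts[i, ])
  })
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70") +
    ggplot2::geom_vline(data = tab,
                        ggplot2::aes(xintercept = .data$x_obs),
                        colour = "red") +
    ggplot2::facet_grid(timing_class ~ class_index,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "IZ-boundary colocalization count", y = "null replicates") +
    ggplot2::theme_minimal()
}

#' Aggregate peak analysis map
#'
#' @param x An `apa_result` (see [aggregate_peak_analysis()]).
#' @param class Which class map to draw (name or index; default first).
#' @param ... Unused.
#' @return A ggplot of the average O/E map.
#' @export
plot_apa <- function(x, class = 1, ...) {
  entry <- x[[class]]
  m <- entry$map
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$oe <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$oe)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(midpoint = 1, name = "O/E") +
    ggplot2::labs(subtitle = paste0("n = ", entry$n)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Insulation track with called boundaries
#'
#' @param insulation Tibble from [compute_insulation()].
#' @param boundaries Optional boundary tibble (`bin`) to mark.
#' @return A ggplot.
#' @export
plot_insulation <- function(insulation, boundaries = NULL) {
  p <- ggplot2::ggplot(insulation, ggplot2::aes(x = .data$bin, y = .data$score)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "bin", y = "insulation (log2)") +
    ggplot2::theme_minimal()
  if (!is.null(boundaries)) {
    p <- p + ggplot2::geom_vline(xintercept = boundaries$bin,
                                 linetype = "dotted", colour = "red")
  }
  p
}
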