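# ggplot2 display helpers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Accuracy curves against the number of selected features
#'
#' @param object A `plv_kcurve` from [accuracy_vs_k()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plv_kcurve
#' @export
autoplot.plv_kcurve <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves, -"k",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = "dashed") +
    ggplot2::labs(x = "number of selected features k", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of bootstrap ratios
#'
#' @param object A `plv_bsr`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plv_bsr
#' @export
autoplot.plv_bsr <- function(object, bins = 60, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::labs(x = "bootstrap ratio", y = "elements") +
    ggplot2::theme_minimal()
}

#' Null accuracy distribution with the observed value
#'
#' @param object A `plv_null`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plv_null
#' @export
autoplot.plv_null <- function(object, bins = 20, ...) {
  ggplot2::ggplot(tidy.plv_null(object), ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "null accuracy", y = "permutations") +
    ggplot2::theme_minimal()
}

#' Tail-count profile across frequencies
#'
#' Number of elements in the lower and upper bootstrap-ratio tails per
#' grid frequency, on a log frequency axis.
#'
#' @param tails Output of [tail_counts()].
#' @return A ggplot.
#' @export
plot_tail_counts <- function(tails) {
  long <- tidyr::pivot_longer(tails, c("lower_tail", "upper_tail"),
                              names_to = "tail", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frequency_hz, y = .data$count,
                                     colour = .data$tail)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "connections in tail",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Connectivity (or bootstrap-ratio map) heatmap
#'
#' @param m A symmetric region x region matrix, e.g. from
#'   [connectivity_matrix()] or [band_threshold_map()].
#' @param title Optional plot title.
#' @return A ggplot.
#' @export
plot_connectivity_matrix <- function(m, title = NULL) {
  df <- tibble::tibble(
    row = factor(rep(rownames(m), times = ncol(m)), levels = rev(rownames(m))),
    col = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
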