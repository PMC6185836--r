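#' @rdname heterosis_table
#' @param x,object A `heterosis_tbl`.
#' @param ... Unused.
#' @export
tidy.heterosis_tbl <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "heterosis_tbl")
  out
}

#' @rdname heterosis_table
#' @export
glance.heterosis_tbl <- function(x, ...) {
  x |>
    dplyr::group_by(.data$population, .data$trait) |>
    dplyr::summarise(
      n_hybrids = dplyr::n(),
      mean_mph = mean(.data$mph, na.rm = TRUE),
      mean_mph_abs = mean(.data$mph_abs, na.rm = TRUE),
      mean_bph = mean(.data$bph, na.rm = TRUE),
      frac_positive_mph = mean(.data$mph > 0, na.rm = TRUE),
      n_exceed_best = sum(.data$exceeds_best, na.rm = TRUE),
      .groups = "drop"
    )
}

#' @rdname heterosis_table
#' @export
autoplot.heterosis_tbl <- function(object, ...) {
  df <- dplyr::filter(object, is.finite(.data$mph))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mph, fill = .data$population)) +
    ggplot2::geom_histogram(
      position = "identity", alpha = 0.6,
      bins = 30
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait), scales = "free") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "mid-parent heterosis (%)", y = "hybrids",
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}
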