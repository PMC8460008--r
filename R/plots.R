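#' Plot a simulated trajectory
#'
#' Time course of the group count, total cells, and wild-type / mutant
#' cells, with an optional moving average overlay (the same 200-point
#' window used for steady-state detection).
#'
#' @param object A `fragsim` object.
#' @param ma_window Moving-average window (0 disables the overlay).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fragsim
#' @export
autoplot.fragsim <- function(object, ma_window = 200, ...) {
  tr <- object$trajectory |>
    dplyr::select("time", "n_groups", "n_cells", "n_wt", "n_mut") |>
    tidyr::pivot_longer(-"time", names_to = "series", values_to = "value")
  p <- ggplot2::ggplot(tr, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(alpha = 0.45) +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time (cell generations)", y = NULL,
                  title = sprintf("termination: %s", object$termination)) +
    ggplot2::theme_minimal()
  if (ma_window > 0 && nrow(object$trajectory) >= ma_window) {
    sm <- tr |>
      dplyr::group_by(.data$series) |>
      dplyr::mutate(value = zoo::rollmean(.data$value, ma_window,
                                          fill = NA, align = "right")) |>
      dplyr::ungroup()
    p <- p + ggplot2::geom_line(data = sm, colour = "firebrick", na.rm = TRUE)
  }
  p
}

#' @rdname autoplot.fragsim
#' @method autoplot fragevo
#' @export
autoplot.fragevo <- function(object, ...) {
  tr <- object$trajectory |>
    dplyr::select("time", "mean_s", "mean_n") |>
    tidyr::pivot_longer(-"time", names_to = "trait", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$trait)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (cell generations)", y = "community mean trait",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a quantity over the strategy triangle
#'
#' Displays a scan result (e.g. steady-state productivity from
#' [strategy_scan()], or `log10` maximum mutation rate from
#' [sensitivity_sweep()]) as a tile map over `(s, n)`, with the triangle
#' boundary marked.
#'
#' @param tbl A tibble with columns `s`, `n`, and the value column.
#' @param value Column to map to fill (string).
#' @return A ggplot object.
#' @export
plot_strategy_space <- function(tbl, value) {
  stopifnot(value %in% names(tbl))
  tri <- tibble::tibble(s = c(0, 0.5, 0), n = c(0, 0.5, 1))
  ggplot2::ggplot(tbl, ggplot2::aes(.data$s, .data$n)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[value]])) +
    ggplot2::geom_path(data = tri, linetype = 2, colour = "grey40") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_cartesian(xlim = c(0, 0.5), ylim = c(0, 1)) +
    ggplot2::labs(x = "s (offspring-size fraction)",
                  y = "n (transmitted fraction)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
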