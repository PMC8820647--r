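#' Plot a simulated trajectory
#'
#' Tumor and CAR T-cell index over time, with the Dex concentration in a
#' lower panel.
#'
#' @param object A `carrgo_sim` tibble from [carrgo_simulate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.carrgo_sim <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(c("x_ci", "y_ci", "dex_ugml"),
                        names_to = "series", values_to = "value") |>
    dplyr::mutate(series = factor(
      dplyr::recode(.data$series, x_ci = "tumor (CI)",
                    y_ci = "CAR T (CI)", dex_ugml = "Dex (ug/ml)"),
      levels = c("tumor (CI)", "CAR T (CI)", "Dex (ug/ml)")))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_hr, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$series), scales = "free_y") +
    ggplot2::labs(x = "time since treatment (h)", y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_bw()
}

#' Plot a bifurcation diagram
#'
#' Real and imaginary parts of the coexistence eigenvalues over time.
#' Dashed segments mark unstable stretches; vertical lines mark Hopf
#' crossings.
#'
#' @param object A `carrgo_bifurcation` tibble from [bifurcation_diagram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.carrgo_bifurcation <- function(object, ...) {
  hopf <- attr(object, "hopf_times_hr")
  long <- as_tibble(object) |>
    dplyr::mutate(unstable = grepl("unstable", .data$label)) |>
    tidyr::pivot_longer(c("re_lambda_plus", "im_lambda_plus",
                          "re_lambda_minus", "im_lambda_minus"),
                        names_to = "component", values_to = "value") |>
    dplyr::mutate(part = ifelse(grepl("^re", .data$component),
                                "Re(lambda)", "Im(lambda)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(
    .data$time_hr, .data$value, colour = .data$component,
    linetype = .data$unstable)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$part), ncol = 1,
                        scales = "free_y") +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid",
                                              `TRUE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = "time since treatment (h)", y = "1/day",
                  colour = NULL) +
    ggplot2::theme_bw()
  if (length(hopf)) {
    p <- p + ggplot2::geom_vline(xintercept = hopf, colour = "grey40",
                                 linetype = "dotted")
  }
  p
}

#' Threshold scatter of outcome records
#'
#' Equilibrium ratio `theta/kappa2` against initial Dex concentration,
#' coloured by cell line and shaped by E:T ratio, with the decision
#' threshold drawn as a horizontal line. Dex-free conditions are placed one
#' decade below the smallest non-zero concentration.
#'
#' @param records An [outcome_records()] tibble.
#' @param threshold Threshold to draw; defaults to the value stored in
#'   `records`.
#' @return A ggplot object.
#' @export
plot_threshold <- function(records, threshold = NULL) {
  stopifnot(is.data.frame(records), "ratio" %in% names(records))
  if (is.null(threshold)) threshold <- records$threshold[1]
  pos <- records$dex0_ugml[records$dex0_ugml > 0]
  zero_at <- if (length(pos)) min(pos) / 10 else 1e-5
  df <- dplyr::mutate(records, dex_plot = ifelse(.data$dex0_ugml == 0,
                                                 zero_at, .data$dex0_ugml))
  ggplot2::ggplot(df, ggplot2::aes(.data$dex_plot, .data$ratio,
                                   colour = .data$cell_line,
                                   shape = .data$et_ratio)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "initial Dex (ug/ml; leftmost = none)",
                  y = "theta / kappa2 (CI)",
                  colour = "cell line", shape = "E:T") +
    ggplot2::theme_bw()
}
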