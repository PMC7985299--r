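# Plotting helpers (ggplot2). Decoration over the tabular results; the
# numbers always come from the tabular interfaces.

#' Per-patient adipocyte size distribution plot
#'
#' Jittered per-object areas with the per-patient 75th percentile marked,
#' the plot style used to present patient-level adipocyte populations.
#'
#' @param objects Measured object tibble (needs `area_um2`; `patient_id`
#'   optional; rows with `qc_pass == FALSE` are dropped when present).
#' @return A ggplot object.
#' @export
plot_adipocyte_distribution <- function(objects) {
  if ("qc_pass" %in% names(objects))
    objects <- dplyr::filter(objects, .data$qc_pass)
  if (!"patient_id" %in% names(objects))
    objects <- dplyr::mutate(objects, patient_id = "patient")
  p75 <- objects |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(p75 = stats::quantile(.data$area_um2, 0.75, names = FALSE),
                     .groups = "drop")
  ggplot2::ggplot(objects, ggplot2::aes(x = .data$patient_id,
                                        y = .data$area_um2)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = p75, ggplot2::aes(y = .data$p75),
                        colour = "red", shape = 95, size = 10) +
    ggplot2::labs(x = NULL, y = expression("Adipocyte area" ~ (mu * m^2)),
                  caption = "red bar: 75th percentile") +
    ggplot2::theme_minimal()
}

#' Forest plot of conditional logistic odds ratios
#'
#' @param object A `clr_fit`.
#' @param ... Unused.
#' @return A ggplot object (log-scaled OR axis with Wald 95\% CIs).
#' @exportS3Method ggplot2::autoplot
autoplot.clr_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cumulative-incidence curves
#'
#' @param curves Output of [group_specific_incidence()] or a single curve
#'   from [expected_cumulative_incidence()].
#' @return A ggplot object.
#' @export
plot_incidence_curves <- function(curves) {
  if (!"group" %in% names(curves))
    curves <- dplyr::mutate(curves, group = "overall")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$t, y = 100 * .data$ci,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Years since diagnosis", y = "Cumulative incidence (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
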