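# ggplot2 presentation layer. Figures are thin views over the summary
# tibbles; all numbers shown are computed by risk_summary().

risk_palette <- c(safer = "#2166ac", average = "grey55", riskier = "#e08214")

#' Plot posterior summaries of a risk summary
#'
#' Point-interval plot of posterior means and 95% credible intervals per
#' scope, coloured by the safer/average/riskier classification, with the
#' facility reference average (and its interval) as vertical lines.
#'
#' @param object A [risk_summary()] tibble.
#' @param scope Which scopes to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot risk_summary
#' @export
autoplot.risk_summary <- function(object,
                                  scope = c("turbine", "month", "turbine_month"),
                                  ...) {
  scope <- match.arg(scope, several.ok = TRUE)
  ov <- dplyr::filter(object, .data$scope == "overall")
  df <- dplyr::filter(tibble::as_tibble(object), .data$scope %in% !!scope) |>
    dplyr::mutate(label = dplyr::coalesce(
      paste(dplyr::coalesce(.data$turbine_id, ""), dplyr::coalesce(.data$month_key, ""))),
      label = trimws(.data$label)) |>
    dplyr::arrange(.data$posterior_mean) |>
    dplyr::mutate(label = factor(.data$label, levels = unique(.data$label)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$posterior_mean, y = .data$label,
                                   colour = .data$class)) +
    ggplot2::geom_vline(xintercept = ov$posterior_mean, linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = c(ov$cri_low, ov$cri_high),
                        linetype = "dotted", linewidth = 0.3) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$cri_low, xmax = .data$cri_high),
                            height = 0, linewidth = 0.3) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = risk_palette) +
    ggplot2::facet_wrap(~scope, scales = "free_y") +
    ggplot2::labs(x = "probability of rotor-swept-zone entry", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Map of turbines coloured by risk classification
#'
#' @param turbines A [turbine_table()].
#' @param summary A [risk_summary()] tibble (its `turbine` scope is used).
#' @return A ggplot object.
#' @export
plot_risk_map <- function(turbines, summary) {
  cls <- summary |>
    dplyr::filter(.data$scope == "turbine") |>
    dplyr::select("turbine_id", "class", "posterior_mean")
  df <- dplyr::left_join(turbines, cls, by = "turbine_id") |>
    dplyr::mutate(class = dplyr::coalesce(.data$class, "average"))
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, colour = .data$class,
                                   shape = .data$model_name)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = risk_palette) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude", colour = NULL, shape = NULL) +
    ggplot2::theme_minimal(base_size = 10)
}

#' Per-turbine range of monthly entry probabilities
#'
#' One segment per turbine monitored in more than one month, from its
#' minimum to its maximum monthly posterior-mean probability.
#'
#' @param summary A [risk_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_monthly_range <- function(summary) {
  mr <- headline_stats(summary)$monthly_range |>
    dplyr::arrange(.data$max_month) |>
    dplyr::mutate(turbine_id = factor(.data$turbine_id, levels = .data$turbine_id))
  ggplot2::ggplot(mr, ggplot2::aes(y = .data$turbine_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$min_month, xend = .data$max_month,
                                       yend = .data$turbine_id), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$min_month), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(x = .data$max_month), colour = "black") +
    ggplot2::labs(x = "monthly probability of entry (posterior mean)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
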