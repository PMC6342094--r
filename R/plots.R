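# ggplot2 displays for scenario summaries and CI bias reports.

#' Plot the per-replicate correlation distribution of a scenario
#'
#' Histogram of the replicate correlations, shaded by sign and significance
#' at the scenario's alpha — a visual companion to the tallies in
#' [glance()].
#'
#' @param object A `scenario_summary` from [run_scenario()].
#' @param bins Number of histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scenario_summary
#' @export
autoplot.scenario_summary <- function(object, bins = 30, ...) {
  d <- object$per_replicate |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::mutate(
      outcome = dplyr::case_when(
        .data$p_two_tailed < object$config$alpha & .data$r < 0 ~
          "significant negative",
        .data$p_two_tailed < object$config$alpha ~ "significant positive",
        TRUE ~ "not significant"
      )
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, fill = .data$outcome)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(
      "significant negative" = "#b2182b",
      "significant positive" = "#2166ac",
      "not significant" = "grey70"
    )) +
    ggplot2::labs(
      x = "replicate male-female correlation (r)",
      y = "replicates",
      fill = NULL,
      title = sprintf(
        "%g%% CI, %s uninfected-male fitness",
        100 * object$config$ci_fraction, object$config$male_mode
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot line means behind a CI bias report
#'
#' Scatter of per-line mean standardized male versus female fitness with the
#' regression lines fitted with and without the suspect lines, which are
#' highlighted. CI-affected lines sit in the lower-right corner: high male,
#' low female fitness.
#'
#' @param object A `ci_bias_report` from [ci_bias_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ci_bias_report
#' @export
autoplot.ci_bias_report <- function(object, ...) {
  d <- object$line_means |>
    dplyr::mutate(suspect = .data$line_id %in% object$suspect_lines)
  w <- object$with_suspects
  wo <- object$without_suspects
  intercept_with <- mean(d$mean_female_z) - w$slope * mean(d$mean_male_z)
  kept <- d[!d$suspect, , drop = FALSE]
  intercept_wo <- mean(kept$mean_female_z) - wo$slope * mean(kept$mean_male_z)
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$mean_male_z, y = .data$mean_female_z)
  ) +
    ggplot2::geom_abline(
      intercept = intercept_with, slope = w$slope, colour = "#b2182b"
    ) +
    ggplot2::geom_abline(
      intercept = intercept_wo, slope = wo$slope,
      colour = "#2166ac", linetype = "dashed"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$suspect), size = 2) +
    ggplot2::scale_colour_manual(
      values = c("FALSE" = "grey30", "TRUE" = "#b2182b"),
      labels = c("FALSE" = "other lines", "TRUE" = "suspect (CI) lines")
    ) +
    ggplot2::labs(
      x = "mean male fitness (z)",
      y = "mean female fitness (z)",
      colour = NULL,
      title = sprintf(
        "r_mf = %+.2f with suspects (solid), %+.2f without (dashed)",
        w$r, wo$r
      )
    ) +
    ggplot2::theme_minimal()
}
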