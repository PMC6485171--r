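## ggplot2 helpers for the main result types.

#' Plot mean municipal mortality rates under each scenario
#'
#' Lines of mean municipal rate over time per scenario with 95% credible
#' ribbons, one facet per outcome stratum.
#'
#' @param sim An `esf_simulation` (or a [summarise_rates()] tibble).
#' @param weights Passed to [summarise_rates()].
#' @return A ggplot object.
#' @export
plot_scenario_rates <- function(sim, weights = "unweighted") {
  df <- if (inherits(sim, "esf_simulation")) {
    summarise_rates(sim, weights = weights)
  } else {
    sim
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$mean,
                                   colour = .data$scenario,
                                   fill = .data$scenario)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(~stratum, scales = "free_y") +
    ggplot2::labs(x = "Year",
                  y = "ACSC mortality rate (per 100,000 person-years)",
                  colour = "Scenario", fill = "Scenario") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.esf_simulation <- function(object, ...) {
  plot_scenario_rates(object, ...)
}

#' Plot poverty-quintile rate differences between scenarios
#'
#' @param rd Output of [quintile_rate_difference()].
#' @return A ggplot object.
#' @export
plot_quintile_differences <- function(rd) {
  ggplot2::ggplot(rd, ggplot2::aes(x = factor(.data$quintile),
                                   y = .data$estimate,
                                   colour = .data$comparison)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "Poverty quintile (1 = poorest)",
                  y = "Rate difference (per 100,000)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot black/pardo vs white standardised rate ratios by scenario
#'
#' @param srr Output of [standardised_rate_ratio()].
#' @return A ggplot object.
#' @export
plot_srr <- function(srr) {
  ggplot2::ggplot(srr, ggplot2::aes(x = .data$year, y = .data$estimate,
                                    colour = .data$scenario)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "Year", y = "SRR (black/pardo vs white)",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
}

#' Plot scenario coverage trajectories
#'
#' Mean municipal ESF coverage over time per scenario.
#'
#' @param trajectories Output of [scenario_trajectories()].
#' @return A ggplot object.
#' @export
plot_coverage <- function(trajectories) {
  df <- trajectories %>%
    group_by(.data$scenario, .data$year) %>%
    summarise(coverage = mean(.data$esf_coverage), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$coverage,
                                   colour = .data$scenario)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Year", y = "Mean municipal ESF coverage",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
}
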