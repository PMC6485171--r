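## Inequality metrics: poverty-quintile stratification, the concentration
## index along the municipal poverty gradient, quintile rate differences
## between scenarios, and black/pardo vs white standardised rate ratios.

#' Stratify municipalities into baseline-poverty quintiles
#'
#' Quintiles of the 2010 municipal poverty distribution (1 = poorest,
#' 5 = richest), fixed across all later years. Ties are broken by stable
#' municipality-id order, and quintile sizes differ by at most one
#' municipality.
#'
#' @param panel Panel with `poverty_rate` at the baseline year.
#' @param baseline_year Year defining the distribution (default 2010).
#' @return Tibble `muni_id`, `quintile` of class `esf_quintiles`.
#' @export
quintile_stratify <- function(panel, baseline_year = 2010) {
  check_columns(panel, c("muni_id", "year", "poverty_rate"), "panel")
  base <- panel %>%
    filter(.data$year == baseline_year) %>%
    arrange(.data$muni_id)
  if (nrow(base) == 0) {
    abort(sprintf("panel has no rows for baseline year %d", baseline_year))
  }
  n <- nrow(base)
  # poorest first; ties broken by id order (stable)
  ord <- order(-base$poverty_rate, base$muni_id)
  q <- integer(n)
  q[ord] <- ceiling(seq_len(n) / (n / 5))
  q <- pmin(q, 5L)
  out <- tibble(muni_id = base$muni_id, quintile = as.integer(q))
  class(out) <- c("esf_quintiles", class(out))
  out
}

#' Concentration index of mortality along the poverty gradient
#'
#' `C = 2 * cov_w(rate, R) / mu`, with `R` the population-weighted
#' fractional rank of municipalities ordered from poorest to richest
#' (midpoint convention) and `mu` the weighted mean rate. `C > 0` means
#' mortality concentrated among richer municipalities, `C < 0` among
#' poorer. Always in \[-1, 1\] for non-negative rates.
#'
#' @param rates Municipal mortality rates (>= 0).
#' @param rank_var Ranking variable (poverty rate; larger = poorer =
#'   ranked first).
#' @param weights Municipal weights (population; default equal).
#' @param poorest_first Rank direction (default TRUE).
#' @return Scalar concentration index.
#' @export
concentration_index <- function(rates, rank_var, weights = rep(1, length(rates)),
                                poorest_first = TRUE) {
  if (length(rates) < 2) abort("need >= 2 municipalities")
  w <- weights / sum(weights)
  mu <- sum(w * rates)
  if (mu <= 0) abort("mean rate must be positive")
  R <- fractional_rank(rank_var, weights, poorest_first = poorest_first)
  covw <- sum(w * rates * R) - mu * sum(w * R)
  2 * covw / mu
}

#' Per-quintile rate differences between two scenarios
#'
#' Per draw and poverty quintile, the mean municipal rate under scenario
#' `a` minus under `b`; reported as the mean over draws with 2.5%/97.5%
#' quantiles.
#'
#' @param sim An `esf_simulation` run with quintile information.
#' @param a,b Scenario names.
#' @param years Year(s) aggregated (mean over years per draw;
#'   default 2030).
#' @param stratum Outcome stratum.
#' @return Tibble `quintile`, `comparison`, `stratum`, `estimate`,
#'   `ci_lo`, `ci_hi`.
#' @export
quintile_rate_difference <- function(sim, a, b, years = 2030,
                                     stratum = sim$meta$strata[1]) {
  if (is.null(sim$quintile_draws)) {
    abort("simulation was run without quintile stratification")
  }
  qd <- sim$quintile_draws %>%
    filter(.data$stratum == !!stratum, .data$year %in% years,
           .data$scenario %in% c(a, b))
  if (!all(c(a, b) %in% qd$scenario)) {
    abort("both scenarios must be present in the simulation")
  }
  per_draw <- qd %>%
    group_by(.data$draw, .data$scenario, .data$quintile) %>%
    summarise(mean_rate = mean(.data$mean_rate), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "scenario", values_from = "mean_rate")
  per_draw$rd <- per_draw[[a]] - per_draw[[b]]
  per_draw %>%
    group_by(.data$quintile) %>%
    summarise(estimate = mean(.data$rd),
              ci_lo = quantile(.data$rd, 0.025, names = FALSE),
              ci_hi = quantile(.data$rd, 0.975, names = FALSE),
              .groups = "drop") %>%
    mutate(comparison = paste(a, "vs", b), stratum = stratum,
           .after = "quintile")
}

#' Standardised rate ratio between black/pardo and white mortality
#'
#' Per draw, the mean municipal black/pardo ACSC rate divided by the mean
#' municipal white rate; reported as the mean over draws with 2.5%/97.5%
#' quantiles. Draws with a zero white rate are excluded with a warning.
#' Because the model predicts stratum rates directly (age structure is not
#' modelled), the ratio of predicted stratum rates stands in for an
#' age-standardised ratio.
#'
#' @param sim An `esf_simulation` covering both race strata.
#' @param years Year(s) to report (default 2030).
#' @param scenarios Scenarios to report (default all simulated).
#' @param black,white Stratum names (defaults `acsc_black`, `acsc_white`).
#' @return Tibble `scenario`, `year`, `estimate`, `ci_lo`, `ci_hi`.
#' @export
standardised_rate_ratio <- function(sim, years = 2030,
                                    scenarios = sim$meta$scenarios,
                                    black = "acsc_black",
                                    white = "acsc_white") {
  sd_ <- sim$summary_draws %>%
    filter(.data$year %in% years, .data$scenario %in% scenarios,
           .data$stratum %in% c(black, white))
  if (!all(c(black, white) %in% sd_$stratum)) {
    abort("both race strata must be present in the simulation")
  }
  wide <- sd_ %>%
    select("draw", "scenario", "year", "stratum", "mean_rate") %>%
    tidyr::pivot_wider(names_from = "stratum", values_from = "mean_rate")
  zero <- wide[[white]] == 0
  if (any(zero)) {
    warn(sprintf("excluding %d draw(s) with zero white-stratum rate", sum(zero)))
    wide <- wide[!zero, ]
  }
  wide$srr <- wide[[black]] / wide[[white]]
  wide %>%
    group_by(.data$scenario, .data$year) %>%
    summarise(estimate = mean(.data$srr),
              ci_lo = quantile(.data$srr, 0.025, names = FALSE),
              ci_hi = quantile(.data$srr, 0.975, names = FALSE),
              .groups = "drop")
}

#' Concentration-index comparison between two scenarios
#'
#' Per draw, the percent change in the poverty concentration index of
#' mortality under scenario `a` relative to `b` (magnitudes compared, so
#' a more negative index under `a` counts as "higher concentration among
#' the poor").
#'
#' @inheritParams quintile_rate_difference
#' @return Tibble `year`, `comparison`, `stratum`, `estimate` (percent),
#'   `ci_lo`, `ci_hi`.
#' @export
concentration_change <- function(sim, a, b, years = 2030,
                                 stratum = sim$meta$strata[1]) {
  sd_ <- sim$summary_draws %>%
    filter(.data$stratum == !!stratum, .data$year %in% years,
           .data$scenario %in% c(a, b))
  if (!all(c(a, b) %in% sd_$scenario)) {
    abort("both scenarios must be present in the simulation")
  }
  wide <- sd_ %>%
    select("draw", "scenario", "year", "conc_index") %>%
    tidyr::pivot_wider(names_from = "scenario", values_from = "conc_index")
  wide$change <- 100 * (abs(wide[[a]]) / abs(wide[[b]]) - 1)
  wide %>%
    group_by(.data$year) %>%
    summarise(estimate = mean(.data$change),
              ci_lo = quantile(.data$change, 0.025, names = FALSE),
              ci_hi = quantile(.data$change, 0.975, names = FALSE),
              .groups = "drop") %>%
    mutate(comparison = paste(a, "vs", b), stratum = stratum,
           .after = "year")
}
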