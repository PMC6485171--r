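suppressMessages({
  library(dplyr)
  library(tibble)
})

# Minimal balanced panel with all covariates at zero, so the linear
# predictor reduces to alpha + gamma*(year-2010) + coverage effect.
flat_panel <- function(n_muni = 2, years = 2000:2030, population = 1e5,
                       coverage = 1, race_mix = 0.5, poverty = 0) {
  tidyr::expand_grid(muni_id = sprintf("T%02d", seq_len(n_muni)),
                     year = years) %>%
    mutate(region = "Test", population = population, race_mix = race_mix,
           bfp_coverage = 0, poverty_rate = poverty, log_illiteracy = 0,
           urbanisation = 0, public_beds = 0, private_beds = 0,
           log_private_insurance = 0, log_gdp_pc = 0,
           esf_coverage = coverage, mmp_doctors = 0L)
}

# Effect table with unit covariate rate ratios and degenerate CIs, so only
# the coverage effect and the secular trend act.
unit_effect_table <- function(rr_full = c(acsc_total = 0.75,
                                          nutritional = 0.48,
                                          infectious = 0.79,
                                          cardiovascular = 0.85,
                                          acsc_black = 0.69,
                                          acsc_white = 0.85),
                              gamma = 0, duration_lag = 4) {
  effect_table(
    tibble(stratum = names(rr_full), rr_full = unname(rr_full),
           lo = unname(rr_full), hi = unname(rr_full), gamma = gamma),
    tibble(covariate = esf_covariates(), rr = 1, lo = 1, hi = 1),
    duration_lag = duration_lag
  )
}

# generator settings matching a flat panel: no fixed-effect dispersion, so
# alpha_i = log(baseline rate) exactly
flat_params <- function(baseline_rates, table, n = 2) {
  cohort_params(n_municipalities = n, alpha_sd = 0,
                baseline_rates = baseline_rates, true_effects = table)
}

# Independent brute-force concentration index: explicit midpoint ranks and
# the demeaned weighted-covariance formula, computed with a loop.
bf_concentration <- function(rates, pov, w = rep(1, length(rates))) {
  ord <- order(-pov)
  wn <- w / sum(w)
  R <- numeric(length(w))
  cum <- 0
  for (i in ord) {
    R[i] <- cum + wn[i] / 2
    cum <- cum + wn[i]
  }
  mu <- sum(wn * rates)
  Rbar <- sum(wn * R)
  2 * sum(wn * (rates - mu) * (R - Rbar)) / mu
}

# Small generated cohort shared by several test files (built fresh per
# call; seeded through cohort_params).
small_cohort <- function(n = 100, seed = 20301L, ...) {
  p <- cohort_params(n_municipalities = n, master_seed = seed, ...)
  panel <- generate_cohort(p) %>% assign_mmp_doctors(p)
  list(params = p, panel = panel)
}

# Panel whose 2017-2030 coverage follows a given scenario, with deaths
# generated from the model (identifiable coverage variation for fitting).
scenario_death_panel <- function(n = 100, scenario = "austerity",
                                 table = default_effect_table(),
                                 seed = 20301L, poisson = TRUE,
                                 deaths_seed = NULL) {
  sc <- small_cohort(n, seed = seed)
  pf <- forecast_covariates(sc$panel)
  traj <- scenario_trajectories(pf) %>% filter(.data$scenario == !!scenario)
  pf <- pf %>%
    left_join(traj %>% select("muni_id", "year", cov2 = "esf_coverage"),
              by = c("muni_id", "year")) %>%
    mutate(esf_coverage = ifelse(is.na(.data$cov2), .data$esf_coverage,
                                 .data$cov2)) %>%
    select(-"cov2")
  generate_deaths(pf, table, sc$params, seed = deaths_seed,
                  poisson = poisson)
}
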