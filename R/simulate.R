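## Monte Carlo engine.
##
## Per draw: effect sizes are resampled from distributions calibrated to
## their published confidence intervals (normal on ln(RR) by default),
## observed baseline deaths are redrawn Poisson and the municipality fixed
## effects re-anchored, and the deterministic model is evaluated along
## every scenario trajectory. Means and 2.5%/97.5% quantiles over draws
## are the reported credible summaries.

#' Monte Carlo draw specification
#'
#' @param n_draws Number of draws (study default 10,000; a few hundred is
#'   adequate at desk scale).
#' @param master_seed Integer seed for all engine randomness.
#' @param sample_effects Resample effect sizes from their CI-calibrated
#'   distributions.
#' @param sample_baseline Redraw observed baseline deaths Poisson and
#'   re-anchor fixed effects each draw.
#' @param effect_scale `"log"` (normal on ln RR, keeps rate ratios
#'   positive; default) or `"natural"` (normal on RR).
#' @export
draw_spec <- function(n_draws = 500, master_seed = 1L,
                      sample_effects = TRUE, sample_baseline = TRUE,
                      effect_scale = c("log", "natural")) {
  if (n_draws < 1) abort("n_draws must be >= 1")
  structure(list(n_draws = as.integer(n_draws),
                 master_seed = as.integer(master_seed),
                 sample_effects = sample_effects,
                 sample_baseline = sample_baseline,
                 effect_scale = match.arg(effect_scale)),
            class = "esf_draw_spec")
}

## sigma of the sampling distribution per parameter
effect_sigma <- function(lo, hi, point, scale) {
  if (any(lo > hi)) abort("effect-size CI has lo > hi")
  if (scale == "log") (log(hi) - log(lo)) / (2 * 1.96) else (hi - lo) / (2 * 1.96)
}

#' Sample effect sizes from their CI-calibrated distributions
#'
#' Each rate ratio is drawn from a normal distribution centred on its
#' point estimate with sd `(ln hi - ln lo) / (2 * 1.96)` on the log scale
#' (default), or `(hi - lo) / (2 * 1.96)` on the natural scale. A
#' degenerate interval (`lo == hi`) yields the constant point estimate.
#'
#' @param table [effect_table()].
#' @param n Number of draws.
#' @param seed Optional seed.
#' @param scale `"log"` or `"natural"`.
#' @return Tidy tibble: `draw`, `type` (`rr_full` or `covariate`), `name`,
#'   `rr` (always positive).
#' @export
draw_effects <- function(table, n = 1, seed = NULL,
                         scale = c("log", "natural")) {
  scale <- match.arg(scale)
  stopifnot(inherits(table, "esf_effects"))
  draws <- function() draw_effect_matrices(table, n, scale)
  m <- if (is.null(seed)) draws() else with_seed(seed, draws())
  bind_rows(
    tibble(draw = rep(seq_len(n), times = ncol(m$rr_full)),
           type = "rr_full",
           name = rep(colnames(m$rr_full), each = n),
           rr = as.vector(m$rr_full)),
    tibble(draw = rep(seq_len(n), times = ncol(m$rr_cov)),
           type = "covariate",
           name = rep(colnames(m$rr_cov), each = n),
           rr = as.vector(m$rr_cov))
  )
}

## n x k matrices of sampled rate ratios (positive by construction)
draw_effect_matrices <- function(table, n, scale) {
  s <- table$strata
  cv <- table$covariates
  sig_s <- effect_sigma(s$lo, s$hi, s$rr_full, scale)
  sig_c <- effect_sigma(cv$lo, cv$hi, cv$rr, scale)
  draw_one <- function(point, sig) {
    if (scale == "log") {
      exp(rnorm(n, log(point), sig))
    } else {
      pmax(rnorm(n, point, sig), 1e-8)
    }
  }
  rr_full <- vapply(seq_len(nrow(s)), function(j) draw_one(s$rr_full[j], sig_s[j]),
                    numeric(n))
  rr_cov <- vapply(seq_len(nrow(cv)), function(j) draw_one(cv$rr[j], sig_c[j]),
                   numeric(n))
  if (n == 1) {
    rr_full <- matrix(rr_full, nrow = 1)
    rr_cov <- matrix(rr_cov, nrow = 1)
  }
  colnames(rr_full) <- s$stratum
  colnames(rr_cov) <- cv$covariate
  list(rr_full = rr_full, rr_cov = rr_cov)
}

#' Run the Monte Carlo simulation
#'
#' Evaluates the mortality model along every scenario trajectory under
#' propagated baseline (Poisson) and effect-size uncertainty, reducing
#' each draw to per-(scenario, year, stratum) aggregates: unweighted and
#' population-weighted mean municipal rates, implied death counts, the
#' poverty concentration index, and per-poverty-quintile means.
#' Deterministic given `spec$master_seed`.
#'
#' @param panel Panel with covariates, populations, coverage and observed
#'   `deaths_<stratum>` in the anchoring window.
#' @param trajectories Scenario coverage trajectories
#'   ([scenario_trajectories()]).
#' @param table [effect_table()].
#' @param spec [draw_spec()].
#' @param strata Outcome strata to simulate.
#' @param window Observed years used to anchor fixed effects
#'   (default 2010:2016).
#' @inheritParams coverage_effect
#' @param quintiles Optional [quintile_stratify()]; computed from 2010
#'   poverty when the panel allows it.
#' @param keep_rates Keep the full draws x municipalities rate array
#'   (memory-heavy; default FALSE).
#' @return An object of class `esf_simulation` with elements
#'   `summary_draws`, `quintile_draws`, optional `rates`, and `meta`.
#' @export
run_simulation <- function(panel, trajectories, table, spec = draw_spec(),
                           strata = "acsc_total", window = 2010:2016,
                           parameterization = "continuous",
                           quintiles = NULL, keep_rates = FALSE) {
  stopifnot(inherits(spec, "esf_draw_spec"))
  panel <- panel %>% arrange(.data$muni_id, .data$year)
  ids <- sort(unique(trajectories$muni_id))
  n <- length(ids)
  if (!setequal(ids, unique(panel$muni_id))) {
    abort("panel and trajectories must cover the same municipalities")
  }
  if (is.null(quintiles) && "poverty_rate" %in% names(panel) &&
      2010 %in% panel$year) {
    quintiles <- quintile_stratify(panel)
  }
  qvec <- if (is.null(quintiles)) rep(1L, n) else
    quintiles$quintile[match(ids, quintiles$muni_id)]
  qmult <- if (is.null(quintiles)) rep(1, n) else
    table$quintile_multipliers[qvec]

  scen_names <- sort(unique(trajectories$scenario))
  years <- sort(unique(trajectories$year))
  covar_names <- table$covariates$covariate

  # --- static pieces per scenario: covariates, coverage weights, ranks ---
  covars <- panel %>%
    select(all_of(c("muni_id", "year", "population", "race_mix",
                    covar_names))) %>%
    distinct(.data$muni_id, .data$year, .keep_all = TRUE)
  pre <- panel %>% filter(.data$year < min(years)) %>%
    select("muni_id", "year", "esf_coverage")

  scen_data <- lapply(scen_names, function(sc) {
    traj <- trajectories %>% filter(.data$scenario == sc) %>%
      arrange(.data$muni_id, .data$year)
    hist <- bind_rows(pre %>% mutate(scenario = sc), traj) %>%
      arrange(.data$muni_id, .data$year)
    hist$duration <- coverage_duration(hist$muni_id, hist$esf_coverage)
    hist <- hist %>% filter(.data$year >= min(years))
    d <- hist %>% left_join(covars, by = c("muni_id", "year"))
    if (anyNA(d[, covar_names])) {
      abort(sprintf("panel lacks covariates for scenario '%s' trajectory years", sc))
    }
    w <- if (parameterization == "categorical") {
      ifelse(d$esf_coverage < 0.7, 0,
             ifelse(d$duration < table$duration_lag, 0.5, 1))
    } else {
      d$esf_coverage * pmin(d$duration / table$duration_lag, 1)
    }
    # rows are sorted by (muni_id, year), so within each year the
    # municipalities appear in ascending id order already
    list(rows = d, X = as.matrix(d[, covar_names]),
         w = w * qmult[match(d$muni_id, ids)],
         t_rel = d$year - 2010,
         year_f = factor(d$year, levels = years),
         year_rows = split(seq_len(nrow(d)), factor(d$year, levels = years)),
         id_idx = match(d$muni_id, ids))
  })
  names(scen_data) <- scen_names

  # per-year population weights and poverty fractional ranks
  pov2010 <- if (!is.null(quintiles)) {
    panel %>% filter(.data$year == 2010) %>% arrange(.data$muni_id) %>%
      pull("poverty_rate")
  } else {
    NULL
  }

  # --- anchoring pieces (observed window) ---
  dur_all <- coverage_duration(panel$muni_id, panel$esf_coverage)
  out_summary <- list()
  out_quint <- list()
  out_rates <- list()

  with_seed(substream(spec$master_seed, "engine"), {
    for (s in strata) {
      dcol <- paste0("deaths_", s)
      check_columns(panel, dcol, "panel")
      inw <- panel$year %in% window & !is.na(panel[[dcol]])
      obs <- panel[inw, ]
      if (nrow(obs) == 0) abort("anchoring window is empty")
      py_obs <- stratum_person_years(obs, s)
      d_obs <- obs[[dcol]]
      obs_id <- factor(obs$muni_id, levels = ids)
      n_obs <- as.vector(base::table(obs_id))
      Xbar <- rowsum(as.matrix(obs[, covar_names]), obs_id) / n_obs
      w_obs <- if (parameterization == "categorical") {
        ifelse(obs$esf_coverage < 0.7, 0,
               ifelse(dur_all[inw] < table$duration_lag, 0.5, 1))
      } else {
        obs$esf_coverage * pmin(dur_all[inw] / table$duration_lag, 1)
      }
      w_obs <- w_obs * qmult[as.integer(obs_id)]
      wbar <- as.vector(rowsum(w_obs, obs_id)) / n_obs
      tbar <- as.vector(rowsum(obs$year - 2010, obs_id)) / n_obs
      gamma <- stratum_row(table, s)$gamma

      eff <- draw_effect_matrices(table, spec$n_draws, spec$effect_scale)
      sd_list <- scen_data
      py_pred <- lapply(sd_list, function(z) {
        stratum_person_years(z$rows, s)
      })

      for (k in seq_len(spec$n_draws)) {
        lnb <- if (spec$sample_effects) log(eff$rr_cov[k, ]) else
          log(table$covariates$rr)
        lnrr <- if (spec$sample_effects) log(eff$rr_full[k, s]) else
          log(stratum_row(table, s)$rr_full)
        d_k <- if (spec$sample_baseline) rpois(length(d_obs), d_obs) else d_obs
        lr_obs <- log((d_k + 0.5 * (d_k == 0)) / py_obs * 1e5)
        lrbar <- as.vector(rowsum(lr_obs, obs_id)) / n_obs
        alpha <- lrbar - gamma * tbar - as.vector(Xbar %*% lnb) - lnrr * wbar

        for (sc in scen_names) {
          z <- sd_list[[sc]]
          lograte <- alpha[z$id_idx] + gamma * z$t_rel +
            as.vector(z$X %*% lnb) + lnrr * z$w
          rate <- exp(lograte)
          py <- py_pred[[sc]]
          deaths <- rate * py / 1e5
          mean_rate <- as.vector(rowsum(rate, z$year_f)) / n
          wsum <- as.vector(rowsum(py, z$year_f))
          wmean_rate <- as.vector(rowsum(rate * py, z$year_f)) / wsum
          deaths_y <- as.vector(rowsum(deaths, z$year_f))
          ci <- if (is.null(pov2010)) rep(NA_real_, length(years)) else {
            vapply(z$year_rows, function(ix) {
              concentration_index(rate[ix], pov2010, py[ix])
            }, numeric(1))
          }
          out_summary[[length(out_summary) + 1]] <- tibble(
            draw = k, scenario = sc, year = years, stratum = s,
            mean_rate = mean_rate, wmean_rate = wmean_rate,
            deaths = deaths_y, person_years = wsum, conc_index = ci
          )
          if (!is.null(quintiles)) {
            qf <- interaction(qvec[z$id_idx], z$year_f, drop = FALSE)
            qn <- as.vector(base::table(qf))
            grid <- expand.grid(quintile = sort(unique(qvec)), year = years)
            out_quint[[length(out_quint) + 1]] <- tibble(
              draw = k, scenario = sc, year = grid$year, stratum = s,
              quintile = grid$quintile,
              mean_rate = as.vector(rowsum(rate, qf)) / qn,
              deaths = as.vector(rowsum(deaths, qf)),
              person_years = as.vector(rowsum(py, qf))
            )
          }
          if (keep_rates) {
            out_rates[[length(out_rates) + 1]] <- tibble(
              draw = k, scenario = sc, stratum = s,
              muni_id = z$rows$muni_id, year = z$rows$year, rate = rate
            )
          }
        }
      }
    }
  })

  structure(
    list(
      summary_draws = bind_rows(out_summary),
      quintile_draws = if (length(out_quint)) bind_rows(out_quint) else NULL,
      rates = if (keep_rates) bind_rows(out_rates) else NULL,
      meta = list(n_draws = spec$n_draws, seed = spec$master_seed,
                  strata = strata, scenarios = scen_names, years = years,
                  n_municipalities = n,
                  sample_effects = spec$sample_effects,
                  sample_baseline = spec$sample_baseline,
                  effect_scale = spec$effect_scale)
    ),
    class = "esf_simulation"
  )
}

#' @export
print.esf_simulation <- function(x, ...) {
  m <- x$meta
  cat("<esf_simulation>\n")
  cat(sprintf("  %d draws | %d municipalities | years %d-%d\n",
              m$n_draws, m$n_municipalities, min(m$years), max(m$years)))
  cat("  scenarios:", paste(m$scenarios, collapse = ", "), "\n")
  cat("  strata:", paste(m$strata, collapse = ", "), "\n")
  invisible(x)
}

#' Summarise simulated rates
#'
#' Mean municipal mortality rate per (scenario, year, stratum): the
#' unweighted (or population-weighted) mean over municipalities, averaged
#' over draws, with 2.5% and 97.5% draw quantiles.
#'
#' @param sim An `esf_simulation`.
#' @param weights `"unweighted"` (mean municipal rate, default) or
#'   `"population"`.
#' @return Tibble `scenario`, `year`, `stratum`, `mean`, `ci_lo`, `ci_hi`.
#' @export
summarise_rates <- function(sim, weights = c("unweighted", "population")) {
  weights <- match.arg(weights)
  col <- if (weights == "unweighted") "mean_rate" else "wmean_rate"
  sim$summary_draws %>%
    group_by(.data$scenario, .data$year, .data$stratum) %>%
    summarise(
      mean = mean(.data[[col]]),
      ci_lo = quantile(.data[[col]], 0.025, names = FALSE),
      ci_hi = quantile(.data[[col]], 0.975, names = FALSE),
      .groups = "drop"
    )
}

#' @export
tidy.esf_simulation <- function(x, weights = "unweighted", ...) {
  summarise_rates(x, weights = weights)
}

#' @export
glance.esf_simulation <- function(x, ...) {
  m <- x$meta
  tibble(n_draws = m$n_draws, seed = m$seed,
         n_municipalities = m$n_municipalities,
         n_scenarios = length(m$scenarios), n_strata = length(m$strata),
         year_min = min(m$years), year_max = max(m$years))
}

#' Ratio of mean municipal rates between two scenarios
#'
#' Per draw, the ratio of (un)weighted mean municipal rates under scenario
#' `a` versus `b`; reported as the mean over draws with 2.5%/97.5%
#' quantiles. Draws with a zero denominator are excluded with a warning.
#'
#' @param sim An `esf_simulation`.
#' @param a,b Scenario names (numerator, denominator).
#' @param years Year(s) to report (default 2030).
#' @param stratum Outcome stratum (default first simulated).
#' @inheritParams summarise_rates
#' @return Tibble `year`, `stratum`, `comparison`, `estimate`, `ci_lo`,
#'   `ci_hi`.
#' @export
scenario_ratio <- function(sim, a, b, years = 2030,
                           stratum = sim$meta$strata[1],
                           weights = c("unweighted", "population")) {
  weights <- match.arg(weights)
  col <- if (weights == "unweighted") "mean_rate" else "wmean_rate"
  sd_ <- sim$summary_draws %>%
    filter(.data$stratum == !!stratum, .data$year %in% years,
           .data$scenario %in% c(a, b))
  if (!all(c(a, b) %in% sd_$scenario)) {
    abort("both scenarios must be present in the simulation")
  }
  wide <- sd_ %>%
    select("draw", "scenario", "year", value = all_of(col)) %>%
    tidyr::pivot_wider(names_from = "scenario", values_from = "value")
  zero <- wide[[b]] == 0
  if (any(zero)) {
    warn(sprintf("excluding %d draw-year(s) with zero denominator rate", sum(zero)))
    wide <- wide[!zero, ]
  }
  wide$ratio <- wide[[a]] / wide[[b]]
  wide %>%
    group_by(.data$year) %>%
    summarise(estimate = mean(.data$ratio),
              ci_lo = quantile(.data$ratio, 0.025, names = FALSE),
              ci_hi = quantile(.data$ratio, 0.975, names = FALSE),
              .groups = "drop") %>%
    mutate(stratum = stratum, comparison = paste(a, "vs", b),
           .after = "year")
}

#' Excess deaths between two scenarios
#'
#' Per draw, the sum over municipalities and years of
#' `(rate_a - rate_b) * person_years / 100,000`; reported as mean and
#' 2.5%/97.5% quantiles over draws. Antisymmetric in (a, b) by
#' construction.
#'
#' @inheritParams scenario_ratio
#' @param years Years summed over (default 2017:2030).
#' @return One-row tibble `comparison`, `stratum`, `estimate`, `ci_lo`,
#'   `ci_hi`.
#' @export
excess_deaths <- function(sim, a, b, years = 2017:2030,
                          stratum = sim$meta$strata[1]) {
  sd_ <- sim$summary_draws %>%
    filter(.data$stratum == !!stratum, .data$year %in% years,
           .data$scenario %in% c(a, b))
  if (!all(c(a, b) %in% sd_$scenario)) {
    abort("both scenarios must be present in the simulation")
  }
  per_draw <- sd_ %>%
    group_by(.data$draw, .data$scenario) %>%
    summarise(deaths = sum(.data$deaths), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "scenario", values_from = "deaths")
  excess <- per_draw[[a]] - per_draw[[b]]
  tibble(comparison = paste(a, "vs", b), stratum = stratum,
         estimate = mean(excess),
         ci_lo = quantile(excess, 0.025, names = FALSE),
         ci_hi = quantile(excess, 0.975, names = FALSE))
}
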