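## Fixed-effects log-linear mortality model.
##
## rate_it = exp( alpha_i + gamma*(year-2010) + sum_k ln(beta_k) x_kit
##                + coverage_effect(coverage_it, duration_it) )
## in deaths per 100,000 person-years. alpha_i are municipality fixed
## effects anchoring predictions to the observed window; gamma is the
## common secular trend; beta_k are covariate rate ratios; the coverage
## effect interpolates the full-consolidated-coverage rate ratio rr_full.

#' Cumulative coverage duration along a trajectory
#'
#' Consecutive years with positive ESF coverage, reset to zero whenever
#' coverage drops to zero. Rows must be ordered by year within
#' municipality.
#'
#' @param ids Municipality ids (contiguous blocks).
#' @param coverage Coverage fractions aligned with `ids`.
#' @return Integer vector of durations (years, including the current one).
#' @export
coverage_duration <- function(ids, coverage) {
  unlist(lapply(split(coverage > 0, factor(ids, levels = unique(ids))),
                function(p) {
                  d <- integer(length(p))
                  run <- 0L
                  for (k in seq_along(p)) {
                    run <- if (p[k]) run + 1L else 0L
                    d[k] <- run
                  }
                  d
                }), use.names = FALSE)
}

#' Coverage contribution to the log mortality rate
#'
#' Continuous parameterization (default): contribution =
#' `coverage * min(duration / L, 1) * ln(rr_full)`, a bilinear ramp through
#' the printed full-coverage anchor. Categorical parameterization (for the
#' duration-effect sensitivity axis): three consolidation classes — no
#' effect below 70% coverage, half the log-effect for fewer than `L` years
#' of programme presence, the full log-effect at >= 70% coverage sustained
#' `L` or more years. The contribution is always <= 0 when `rr_full <= 1`.
#'
#' @param coverage Coverage fraction(s) in \[0, 1\].
#' @param duration Years of sustained programme presence (>= 0).
#' @param table An [effect_table()].
#' @param stratum Outcome stratum.
#' @param parameterization `"continuous"` or `"categorical"`.
#' @param quintile Optional baseline-poverty quintile (1-5) used to apply
#'   the table's per-quintile effectiveness multipliers.
#' @return Log-rate contribution (same length as `coverage`).
#' @export
coverage_effect <- function(coverage, duration, table, stratum,
                            parameterization = c("continuous", "categorical"),
                            quintile = NULL) {
  parameterization <- match.arg(parameterization)
  if (any(coverage < 0 | coverage > 1)) abort("coverage must lie in [0, 1]")
  if (any(duration < 0)) abort("duration must be >= 0")
  row <- stratum_row(table, stratum)
  L <- table$duration_lag
  qm <- if (is.null(quintile)) 1 else table$quintile_multipliers[quintile]
  w <- switch(parameterization,
    continuous = coverage * pmin(duration / L, 1),
    categorical = ifelse(coverage < 0.7, 0, ifelse(duration < L, 0.5, 1))
  )
  w * log(row$rr_full) * qm
}

## Vectorised log-rate kernel shared by generation, prediction and the
## Monte Carlo engine. X columns are selected by the covariate names of
## the table, so column order never matters.
model_log_rate <- function(X, year, alpha, coverage, duration, table,
                           stratum, parameterization = "continuous",
                           quintile = NULL,
                           lnb = log(table$covariates$rr),
                           lnrr_full = log(stratum_row(table, stratum)$rr_full),
                           gamma = stratum_row(table, stratum)$gamma) {
  X <- X[, table$covariates$covariate, drop = FALSE]
  qm <- if (is.null(quintile)) 1 else table$quintile_multipliers[quintile]
  w <- if (parameterization == "categorical") {
    ifelse(coverage < 0.7, 0, ifelse(duration < table$duration_lag, 0.5, 1))
  } else {
    coverage * pmin(duration / table$duration_lag, 1)
  }
  as.vector(alpha + gamma * (year - 2010) + X %*% lnb + w * lnrr_full * qm)
}

#' Expected mortality rate per 100,000 person-years
#'
#' Deterministic model prediction for panel rows. Covariates are taken
#' from `data`; a missing covariate raises an error naming it.
#'
#' @param data Panel rows with `muni_id`, `year` and the model covariates.
#' @param table [effect_table()].
#' @param stratum Outcome stratum.
#' @param fe Fixed effects: tibble (`muni_id`, `stratum`, `alpha`) from
#'   [estimate_fixed_effects()], or a named numeric vector by `muni_id`.
#' @param coverage Coverage fractions (default `data$esf_coverage`).
#' @param duration Programme durations; computed from `coverage` along the
#'   rows when omitted.
#' @inheritParams coverage_effect
#' @return Numeric vector of rates (> 0, deterministic).
#' @export
expected_rate <- function(data, table, stratum, fe,
                          coverage = data$esf_coverage, duration = NULL,
                          parameterization = "continuous", quintile = NULL) {
  check_columns(data, c("muni_id", "year", table$covariates$covariate),
                "data")
  alpha <- fe_vector(fe, stratum)
  missing_fe <- setdiff(unique(data$muni_id), names(alpha))
  if (length(missing_fe) > 0) {
    abort(sprintf("no fixed effect for municipality: %s",
                  paste(head(missing_fe, 5), collapse = ", ")))
  }
  if (is.null(duration)) duration <- coverage_duration(data$muni_id, coverage)
  lr <- model_log_rate(
    X = as.matrix(data[, table$covariates$covariate]),
    year = data$year, alpha = alpha[data$muni_id],
    coverage = coverage, duration = duration, table = table,
    stratum = stratum, parameterization = parameterization,
    quintile = quintile
  )
  exp(lr)
}

fe_vector <- function(fe, stratum) {
  if (is.numeric(fe) && !is.null(names(fe))) return(fe)
  check_columns(fe, c("muni_id", "stratum", "alpha"), "fixed effects")
  sub <- fe[fe$stratum == stratum, ]
  if (nrow(sub) == 0) abort(sprintf("no fixed effects for stratum '%s'", stratum))
  setNames(sub$alpha, sub$muni_id)
}

#' Anchor municipality fixed effects to observed death counts
#'
#' Chooses `alpha_i` so the mean model log-rate over the observation
#' window equals the observed mean log-rate, all other coefficients given.
#' Zero-death municipality-years are continuity-corrected by adding half a
#' death; municipalities whose every observed year is zero are anchored at
#' the continuity floor and flagged in the `flagged` column.
#'
#' @param panel Panel with `deaths_<stratum>` for at least 3 years per
#'   municipality in the window, plus covariates and `esf_coverage`.
#' @param table [effect_table()].
#' @param stratum Outcome stratum.
#' @param window Observation years used for anchoring (default 2010:2016).
#' @inheritParams coverage_effect
#' @return Tibble of class `esf_fe`: `muni_id`, `stratum`, `alpha`,
#'   `flagged`.
#' @export
estimate_fixed_effects <- function(panel, table, stratum,
                                   window = 2010:2016,
                                   parameterization = "continuous",
                                   quintile = NULL) {
  dcol <- paste0("deaths_", stratum)
  check_columns(panel, c("muni_id", "year", "population", "esf_coverage",
                         dcol, table$covariates$covariate), "panel")
  panel <- panel %>% arrange(.data$muni_id, .data$year)
  duration <- coverage_duration(panel$muni_id, panel$esf_coverage)
  inw <- panel$year %in% window & !is.na(panel[[dcol]])
  obs <- panel[inw, ]
  durw <- duration[inw]
  counts <- base::table(obs$muni_id)
  if (any(counts < 3)) {
    abort("each municipality needs observed deaths for >= 3 window years")
  }
  py <- stratum_person_years(obs, stratum)
  if (any(py <= 0)) abort("municipality with zero person-years in window")
  d <- obs[[dcol]]
  lograte_obs <- log((d + 0.5 * (d == 0)) / py * 1e5)
  lin <- model_log_rate(
    X = as.matrix(obs[, table$covariates$covariate]),
    year = obs$year, alpha = 0, coverage = obs$esf_coverage,
    duration = durw, table = table, stratum = stratum,
    parameterization = parameterization, quintile = quintile
  )
  resid <- lograte_obs - lin
  ids <- factor(obs$muni_id, levels = unique(obs$muni_id))
  alpha <- tapply(resid, ids, mean)
  all_zero <- tapply(d, ids, function(x) all(x == 0))
  out <- tibble(muni_id = names(alpha), stratum = stratum,
                alpha = as.numeric(alpha),
                flagged = as.logical(all_zero))
  class(out) <- c("esf_fe", class(out))
  out
}

#' Predict mortality rates along scenario trajectories
#'
#' One deterministic prediction per (municipality, year, scenario,
#' stratum). Programme duration is tracked cumulatively along each
#' scenario's coverage trajectory, with the observed pre-trajectory
#' coverage history counting toward consolidation.
#'
#' @param panel Panel providing covariates for every trajectory year.
#' @param trajectories Tibble `muni_id`, `year`, `scenario`,
#'   `esf_coverage` (e.g. from [scenario_trajectories()]).
#' @param fe Fixed effects tibble covering all requested strata.
#' @param table [effect_table()].
#' @param strata Outcome strata to predict (default all in `fe`).
#' @inheritParams coverage_effect
#' @param quintiles Optional [quintile_stratify()] assignment enabling the
#'   per-quintile effectiveness multipliers.
#' @return Tibble `muni_id`, `year`, `scenario`, `stratum`, `rate`.
#' @export
predict_panel <- function(panel, trajectories, fe, table,
                          strata = unique(fe$stratum),
                          parameterization = "continuous",
                          quintiles = NULL) {
  check_columns(trajectories, c("muni_id", "year", "scenario", "esf_coverage"),
                "trajectories")
  missing_ids <- setdiff(unique(trajectories$muni_id), unique(panel$muni_id))
  if (length(missing_ids) > 0) {
    abort(sprintf("trajectory municipalities absent from panel: %s",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  covars <- panel %>%
    select(all_of(c("muni_id", "year", "population", "race_mix",
                    table$covariates$covariate))) %>%
    distinct(.data$muni_id, .data$year, .keep_all = TRUE)
  pre <- panel %>%
    filter(.data$year < min(trajectories$year)) %>%
    select("muni_id", "year", "esf_coverage")
  out <- lapply(split(trajectories, trajectories$scenario), function(traj) {
    traj <- traj %>% arrange(.data$muni_id, .data$year)
    hist <- bind_rows(
      pre %>% mutate(scenario = traj$scenario[1]),
      traj
    ) %>% arrange(.data$muni_id, .data$year)
    hist$duration <- coverage_duration(hist$muni_id, hist$esf_coverage)
    hist <- hist %>% filter(.data$year >= min(traj$year))
    d <- hist %>% left_join(covars, by = c("muni_id", "year"))
    if (anyNA(d[, table$covariates$covariate])) {
      abort("panel does not provide covariates for every trajectory year")
    }
    q <- if (is.null(quintiles)) NULL else quintiles$quintile[
      match(d$muni_id, quintiles$muni_id)]
    bind_rows(lapply(strata, function(s) {
      tibble(
        muni_id = d$muni_id, year = d$year, scenario = d$scenario,
        stratum = s,
        rate = expected_rate(d, table, s, fe,
                             coverage = d$esf_coverage,
                             duration = d$duration,
                             parameterization = parameterization,
                             quintile = q)
      )
    }))
  })
  bind_rows(out) %>% arrange(.data$scenario, .data$stratum,
                             .data$muni_id, .data$year)
}

#' @export
tidy.esf_fe <- function(x, ...) {
  tibble(term = paste0("alpha.", x$muni_id, ".", x$stratum),
         estimate = x$alpha, flagged = x$flagged)
}
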