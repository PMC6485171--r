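## Synthetic municipal cohort generator.
##
## Emulates the statistical structure of the Brazilian municipal panel the
## analysis assumes: ~5507 municipalities observed 2000-2016, covariate
## cross-sections matched to published 2015 moments, per-municipality
## exponential covariate histories with multiplicative log-normal noise,
## ESF coverage ramping up through the 2000s to a 2016 mean of 80.4%,
## Mais Medicos doctors concentrated in high-poverty municipalities from
## 2013, and Poisson death counts per outcome stratum with black/pardo
## baseline rates above white rates.

#' Parameters of the synthetic cohort generator
#'
#' Defaults are the study conditions: covariate mean/sd targets are the
#' published 2015 municipal moments, 2016 ESF coverage has mean 0.804 and
#' sd 0.235, Mais Medicos doctors start in 2013 with an allocation tilted
#' toward poor municipalities, and death counts are drawn from the mortality
#' model itself (so the model parameters are a recoverable ground truth).
#' `n_municipalities` defaults to a 500-municipality desk scale; the
#' full-scale cohort of 5507 is supported by setting it so.
#'
#' @param n_municipalities Number of municipalities (>= 2).
#' @param years Observed panel years (contiguous; default 2000:2016).
#' @param covariate_targets Tibble with columns `covariate`, `mean`, `sd`
#'   (2015 cross-sectional targets on the panel scale), `kind` (one of
#'   `"fraction"`, `"positive"`, `"log"`) and `lambda` (mean per-year
#'   exponential trend on the natural scale; positive = decline).
#' @param coverage_mean_2016,coverage_sd_2016 Moments of the 2016 ESF
#'   coverage distribution (Beta, truncated to \[0,1\] by construction).
#' @param coverage_ramp_2000 ESF coverage in 2000 as a fraction of the 2016
#'   level (linear ramp in between; the programme scaled up through the
#'   2000s).
#' @param traj_noise_sd Multiplicative log-normal noise sd around the
#'   exponential covariate trajectories.
#' @param lambda_sd Between-municipality sd of the trend rate.
#' @param mmp_start_year First year with Mais Medicos doctors (2013).
#' @param mmp_strength Strength of the poverty-to-doctors association
#'   (exponential tilt on the poverty rank; 0 = no association).
#' @param mmp_doctors_per_capita National mean doctors per inhabitant.
#' @param race_mix_mean,race_mix_sd Moments of the municipal black/pardo
#'   population fraction.
#' @param pop_meanlog,pop_sdlog,pop_growth Log-normal municipal population
#'   size distribution and annual growth rate.
#' @param baseline_rates Named vector of 2010 baseline mortality rates per
#'   100,000 person-years by outcome stratum.
#' @param alpha_sd Between-municipality sd of the log-rate fixed effects.
#' @param true_effects [effect_table()] used to generate deaths.
#' @param master_seed Integer master seed; every generator stage draws from
#'   a deterministic substream of it.
#' @return An object of class `esf_cohort_params`.
#' @export
cohort_params <- function(n_municipalities = 500,
                          years = 2000:2016,
                          covariate_targets = default_covariate_targets(),
                          coverage_mean_2016 = 0.804,
                          coverage_sd_2016 = 0.235,
                          coverage_ramp_2000 = 0.25,
                          traj_noise_sd = 0.05,
                          lambda_sd = 0.015,
                          mmp_start_year = 2013,
                          mmp_strength = 2,
                          mmp_doctors_per_capita = 9e-5,
                          race_mix_mean = 0.52,
                          race_mix_sd = 0.15,
                          pop_meanlog = log(11000),
                          pop_sdlog = 1.2,
                          pop_growth = 0.01,
                          baseline_rates = c(
                            acsc_total = 100, nutritional = 3.5,
                            infectious = 12, cardiovascular = 50,
                            acsc_black = 115, acsc_white = 85
                          ),
                          alpha_sd = 0.3,
                          true_effects = default_effect_table(),
                          master_seed = 20301L) {
  if (n_municipalities < 2) abort("n_municipalities must be >= 2")
  targets <- as_tibble(covariate_targets)
  check_columns(targets, c("covariate", "mean", "sd", "kind", "lambda"),
                "covariate_targets")
  if (any(targets$sd < 0)) abort("covariate sd targets must be >= 0")
  frac <- targets$kind == "fraction"
  if (any(frac & (targets$mean < 0 | targets$mean > 1))) {
    abort("fraction covariate mean targets must lie in [0, 1]")
  }
  infeasible <- frac & targets$sd > 0 &
    targets$sd^2 >= targets$mean * (1 - targets$mean)
  if (any(infeasible)) {
    abort(sprintf(
      "impossible moment target (sd^2 >= mean*(1-mean)) for: %s",
      paste(targets$covariate[infeasible], collapse = ", ")
    ))
  }
  if (coverage_mean_2016 < 0 || coverage_mean_2016 > 1) {
    abort("coverage_mean_2016 must lie in [0, 1]")
  }
  structure(
    list(
      n_municipalities = as.integer(n_municipalities), years = years,
      covariate_targets = targets,
      coverage_mean_2016 = coverage_mean_2016,
      coverage_sd_2016 = coverage_sd_2016,
      coverage_ramp_2000 = coverage_ramp_2000,
      traj_noise_sd = traj_noise_sd, lambda_sd = lambda_sd,
      mmp_start_year = mmp_start_year, mmp_strength = mmp_strength,
      mmp_doctors_per_capita = mmp_doctors_per_capita,
      race_mix_mean = race_mix_mean, race_mix_sd = race_mix_sd,
      pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
      pop_growth = pop_growth,
      baseline_rates = baseline_rates, alpha_sd = alpha_sd,
      true_effects = true_effects,
      master_seed = as.integer(master_seed)
    ),
    class = "esf_cohort_params"
  )
}

#' Default covariate moment and trend targets
#'
#' Means and standard deviations are the published 2015 cross-sectional
#' municipal moments; `lambda` values are package choices giving each
#' covariate a realistic decade trend (poverty and illiteracy falling,
#' urbanisation, insurance and GDP rising).
#' @export
default_covariate_targets <- function() {
  tibble(
    covariate = esf_covariates(),
    mean = c(0.335, 0.138, -2.37, 0.684, 0.13, 0.04, -5.62, -4.70),
    sd   = c(0.221, 0.153, 0.79, 0.222, 0.21, 0.10, 1.62, 0.71),
    kind = c("fraction", "fraction", "log", "fraction",
             "positive", "positive", "log", "log"),
    lambda = c(-0.010, 0.060, 0.040, -0.005, 0.010, 0.000, -0.010, -0.020)
  )
}

## Moment-matched cross-sectional draws. Fractions use a Beta with the
## target mean/sd (guarantees [0,1] and the exact first two moments);
## non-negative quantities a Gamma; log-scale covariates a Normal on the
## stored (log) scale. sd = 0 collapses to the degenerate constant.
draw_cross_section <- function(n, mean, sd, kind) {
  if (sd == 0) return(rep(mean, n))
  switch(kind,
    fraction = {
      v <- sd^2
      k <- mean * (1 - mean) / v - 1
      rbeta(n, shape1 = mean * k, shape2 = (1 - mean) * k)
    },
    positive = {
      if (mean <= 0) return(rep(0, n))
      rgamma(n, shape = mean^2 / sd^2, rate = mean / sd^2)
    },
    log = rnorm(n, mean, sd),
    abort(sprintf("unknown covariate kind '%s'", kind))
  )
}

## Exponential trajectory on the natural (positive) scale around a 2015
## anchor, with multiplicative log-normal noise everywhere except the
## anchor year (so cross-sectional moments hold exactly there).
trajectory <- function(anchor_value, lambda, years, noise_sd,
                       anchor_year = 2015) {
  t_rel <- years - anchor_year
  noise <- rnorm(length(years), 0, noise_sd)
  noise[t_rel == 0] <- 0
  anchor_value * exp(-lambda * t_rel + noise)
}

#' Generate the synthetic municipal panel (2000-2016)
#'
#' Draws municipality-level attributes and covariate histories following
#' per-municipality exponential trends with multiplicative noise, anchored
#' so that the 2015 cross-sectional moments match the configured targets.
#' Deterministic given `params$master_seed`.
#'
#' @param params An [cohort_params()] object.
#' @return Tibble with one row per municipality-year: `muni_id`, `region`,
#'   `year`, `population`, `race_mix`, the eight model covariates,
#'   `esf_coverage` and `mmp_doctors` (zero until
#'   [assign_mmp_doctors()] is applied).
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "esf_cohort_params"))
  n <- params$n_municipalities
  years <- params$years
  with_seed(substream(params$master_seed, "cohort"), {
    ids <- sprintf("M%05d", seq_len(n))
    region <- sample(
      c("North", "Northeast", "Southeast", "South", "Centre-West"),
      n, replace = TRUE, prob = c(0.081, 0.322, 0.299, 0.214, 0.084)
    )
    race_mix <- draw_cross_section(n, params$race_mix_mean,
                                   params$race_mix_sd, "fraction")
    pop0 <- exp(rnorm(n, params$pop_meanlog, params$pop_sdlog))

    panel <- tidyr::expand_grid(muni_id = ids, year = years)
    panel$region <- rep(region, each = length(years))
    panel$race_mix <- rep(race_mix, each = length(years))
    panel$population <- pmax(
      round(rep(pop0, each = length(years)) *
              (1 + params$pop_growth)^(panel$year - 2000)),
      1
    )

    for (j in seq_len(nrow(params$covariate_targets))) {
      tg <- params$covariate_targets[j, ]
      x2015 <- draw_cross_section(n, tg$mean, tg$sd, tg$kind)
      natural2015 <- if (tg$kind == "log") exp(x2015) else x2015
      lam <- rnorm(n, tg$lambda, params$lambda_sd)
      vals <- unlist(lapply(seq_len(n), function(i) {
        trajectory(natural2015[i], lam[i], years, params$traj_noise_sd)
      }))
      panel[[tg$covariate]] <- switch(tg$kind,
        fraction = clip(vals, 0, 1),
        positive = vals,
        log = log(pmax(vals, 1e-12))
      )
    }

    cov16 <- draw_cross_section(n, params$coverage_mean_2016,
                                params$coverage_sd_2016, "fraction")
    ramp <- params$coverage_ramp_2000 +
      (1 - params$coverage_ramp_2000) * (years - min(years)) /
      (max(years) - min(years))
    cov_noise <- matrix(rnorm(n * length(years), 0, params$traj_noise_sd),
                        nrow = n)
    cov_noise[, length(years)] <- 0  # 2016 anchor exact
    cov <- t(vapply(seq_len(n), function(i) {
      clip(cov16[i] * ramp * exp(cov_noise[i, ]), 0, 1)
    }, numeric(length(years))))
    panel$esf_coverage <- as.vector(t(cov))
    panel$mmp_doctors <- 0L
    as_tibble(panel[, c("muni_id", "region", "year", "population",
                        "race_mix", params$covariate_targets$covariate,
                        "esf_coverage", "mmp_doctors")])
  })
}

#' Allocate Mais Medicos doctors to municipalities
#'
#' Doctors appear from `mmp_start_year` (2013) onward with a per-capita
#' intensity increasing exponentially in the municipality's baseline
#' poverty rank, then Poisson counts: underserved (poor) municipalities
#' receive systematically more doctors per inhabitant. A strength of zero
#' makes the allocation independent of poverty.
#'
#' @param panel Panel from [generate_cohort()]; must contain `poverty_rate`.
#' @param params [cohort_params()] object.
#' @return The panel with `mmp_doctors` filled for years >= the start year.
#' @export
assign_mmp_doctors <- function(panel, params = cohort_params()) {
  check_columns(panel, c("muni_id", "year", "population", "poverty_rate"),
                "panel")
  base_year <- if (2010 %in% panel$year) 2010 else min(panel$year)
  base <- panel %>%
    filter(.data$year == base_year) %>%
    arrange(.data$muni_id)
  n <- nrow(base)
  with_seed(substream(params$master_seed, "mmp"), {
    pov_rank <- (rank(base$poverty_rate, ties.method = "first") - 0.5) / n
    tilt <- exp(params$mmp_strength * (pov_rank - 0.5))
    # normalise so the population-weighted mean per-capita rate is preserved
    rate_pc <- params$mmp_doctors_per_capita * tilt *
      sum(base$population) / sum(tilt * base$population)
    doctors <- rpois(n, rate_pc * base$population)
    alloc <- tibble(muni_id = base$muni_id, .mmp_n = doctors)
    panel %>%
      left_join(alloc, by = "muni_id") %>%
      mutate(mmp_doctors = ifelse(.data$year >= params$mmp_start_year,
                                  .data$.mmp_n, 0L)) %>%
      select(-".mmp_n")
  })
}

#' Person-years at risk for an outcome stratum
#'
#' Race-stratified outcomes split municipal person-years by the black/pardo
#' population fraction; cause-group and overall outcomes use the full
#' population.
#' @param panel Municipal panel with `population` (and `race_mix` for race
#'   strata).
#' @param stratum Outcome stratum name.
#' @export
stratum_person_years <- function(panel, stratum) {
  switch(stratum,
    acsc_black = panel$population * panel$race_mix,
    acsc_white = panel$population * (1 - panel$race_mix),
    panel$population
  )
}

#' Draw synthetic death counts from the mortality model
#'
#' Municipality fixed effects are drawn around the configured baseline
#' stratum rates (net of each municipality's 2010 covariate contribution),
#' expected rates are computed from the same log-linear model used for
#' prediction, and deaths are independent Poisson draws per outcome
#' stratum, capped at the stratum person-years.
#'
#' @param panel Panel with covariates and `esf_coverage`.
#' @param effects [effect_table()] used as the generating truth.
#' @param params [cohort_params()] supplying baseline rates and the fixed
#'   effect dispersion.
#' @param seed Integer seed; defaults to a substream of the master seed.
#' @param poisson Draw Poisson counts (default); `FALSE` stores the exact
#'   expected deaths (non-integer), useful for noise-free parameter
#'   recovery checks.
#' @return The panel with one `deaths_<stratum>` column per stratum, plus
#'   attributes `true_alpha` (the generating fixed effects) and
#'   `true_effects`.
#' @export
generate_deaths <- function(panel, effects = params$true_effects,
                            params = cohort_params(), seed = NULL,
                            poisson = TRUE) {
  check_columns(panel, c("muni_id", "year", "population", "esf_coverage",
                         effects$covariates$covariate), "panel")
  if (is.null(seed)) seed <- substream(params$master_seed, "deaths")
  strata <- intersect(names(params$baseline_rates), effects$strata$stratum)
  if (length(strata) == 0) abort("no stratum has both a baseline rate and effects")
  panel <- panel %>% arrange(.data$muni_id, .data$year)
  duration <- coverage_duration(panel$muni_id, panel$esf_coverage)
  x2010 <- panel %>% filter(.data$year == 2010) %>% arrange(.data$muni_id)
  if (nrow(x2010) == 0) x2010 <- panel %>% filter(.data$year == min(.data$year))
  X2010 <- as.matrix(x2010[, effects$covariates$covariate])
  lnb <- log(effects$covariates$rr)
  ids <- x2010$muni_id
  alpha_list <- list()
  with_seed(seed, {
    for (s in strata) {
      base <- params$baseline_rates[[s]]
      alpha <- if (base <= 0) {
        rep(-Inf, length(ids))
      } else {
        log(base) - as.vector(X2010 %*% lnb) +
          rnorm(length(ids), 0, params$alpha_sd)
      }
      names(alpha) <- ids
      alpha_list[[s]] <- alpha
      lr <- model_log_rate(
        X = as.matrix(panel[, effects$covariates$covariate]),
        year = panel$year, alpha = alpha[panel$muni_id],
        coverage = panel$esf_coverage, duration = duration,
        table = effects, stratum = s
      )
      py <- stratum_person_years(panel, s)
      mu <- exp(lr) * py / 1e5
      deaths <- if (poisson) pmin(rpois(nrow(panel), mu), floor(py)) else mu
      panel[[paste0("deaths_", s)]] <- deaths
    }
  })
  attr(panel, "true_alpha") <- bind_rows(lapply(strata, function(s) {
    tibble(muni_id = ids, stratum = s, alpha = unname(alpha_list[[s]]))
  }))
  attr(panel, "true_effects") <- effects
  panel
}
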