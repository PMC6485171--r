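## Policy coverage scenarios 2017-2030.
##
## Each municipality's observed 2016 ESF coverage (and the share of it
## contributed by Mais Medicos doctors) is mapped to a 2017-2030 coverage
## trajectory under four policies:
##   status_quo        coverage frozen at the 2016 level
##   austerity         coverage shrinks by a common relative multiplier
##                     path calibrated to the fiscal-contraction forecasts
##   austerity_mmp_end as austerity, with the Mais Medicos contribution
##                     removed at the termination year (default 2019)
##   uhc               linear ramp to 100% coverage in every municipality
##                     by 2030

#' Scenario names
#' @export
esf_scenarios <- function() {
  c("status_quo", "austerity", "austerity_mmp_end", "uhc")
}

#' Mais Medicos contribution to municipal ESF coverage
#'
#' One doctor covers 3450 inhabitants (Ministry of Health norm), capped by
#' the municipality's total coverage.
#'
#' @param doctors Doctor counts (>= 0).
#' @param population Municipal population (> 0).
#' @param total_coverage Total ESF coverage used as the cap.
#' @return Coverage fraction contributed by the programme.
#' @export
mmp_coverage_contribution <- function(doctors, population,
                                      total_coverage = 1) {
  if (any(population <= 0)) abort("population must be positive")
  if (any(doctors < 0)) abort("doctor counts must be non-negative")
  pmin(doctors * 3450 / population, total_coverage)
}

#' Build an austerity decline path from anchor factors
#'
#' Log-linear interpolation between anchor years of multipliers relative
#' to 2016 coverage. The default anchors reproduce the forecast mean
#' coverage declines of the fiscal-contraction scenario (82.7% of the 2016
#' level by 2020, 47.0% by 2030, i.e. mean municipal coverage falling from
#' 80.4% to 66.5% and 37.8%). A `severity` exponent scales the decline for
#' sensitivity analysis (`path^severity`; 1 = calibrated path).
#'
#' @param anchors Named numeric vector or tibble (`year`, `factor`);
#'   must include 2016 with factor 1 and factors in (0, 1].
#' @param years Years to cover (default 2016:2030).
#' @param severity Decline severity exponent (default 1).
#' @return Tibble with `year`, `factor`, non-increasing in year.
#' @export
make_decline_path <- function(anchors = c("2016" = 1, "2020" = 0.665 / 0.804,
                                          "2030" = 0.378 / 0.804),
                              years = 2016:2030, severity = 1) {
  if (is.data.frame(anchors)) {
    a_years <- anchors$year
    a_fac <- anchors$factor
  } else {
    a_years <- as.numeric(names(anchors))
    a_fac <- unname(anchors)
  }
  ord <- order(a_years)
  a_years <- a_years[ord]
  a_fac <- a_fac[ord]
  if (!(2016 %in% a_years) || a_fac[a_years == 2016] != 1) {
    abort("anchors must include 2016 with factor 1")
  }
  if (any(a_fac <= 0 | a_fac > 1)) abort("anchor factors must lie in (0, 1]")
  if (is.unsorted(rev(a_fac))) {
    abort("anchor factors must be non-increasing over years for a decline path")
  }
  if (length(a_years) == 1) {
    fac <- rep(1, length(years))
  } else {
    fac <- exp(stats::approx(a_years, log(a_fac), xout = years, rule = 2)$y)
  }
  tibble(year = years, factor = fac^severity)
}

#' Scenario specification
#'
#' @param name One of [esf_scenarios()].
#' @param decline_path Tibble (`year`, `factor`) for the austerity kinds;
#'   default [make_decline_path()].
#' @param mmp_termination_year Year the Mais Medicos contribution is
#'   removed under `austerity_mmp_end` (default 2019).
#' @param target_year Year full coverage is reached under `uhc`
#'   (default 2030).
#' @return An object of class `esf_scenario`.
#' @export
scenario_spec <- function(name, decline_path = NULL,
                          mmp_termination_year = 2019,
                          target_year = 2030) {
  if (!name %in% esf_scenarios()) {
    abort(sprintf("unknown scenario '%s' (expected one of: %s)",
                  name, paste(esf_scenarios(), collapse = ", ")))
  }
  if (name %in% c("austerity", "austerity_mmp_end") && is.null(decline_path)) {
    decline_path <- make_decline_path()
  }
  structure(
    list(name = name, decline_path = decline_path,
         mmp_termination_year = mmp_termination_year,
         target_year = target_year),
    class = "esf_scenario"
  )
}

#' Apply a policy scenario to the panel
#'
#' Maps each municipality's 2016 coverage (and Mais Medicos contribution)
#' to a coverage trajectory over `years`. All trajectories are clipped to
#' \[0, 1\].
#'
#' @param panel Panel containing 2016 `esf_coverage`, `population` and
#'   `mmp_doctors`.
#' @param spec An [scenario_spec()] (or a scenario name, for defaults).
#' @param years Trajectory years (default 2017:2030).
#' @return Tibble `muni_id`, `year`, `scenario`, `esf_coverage`.
#' @export
apply_scenario <- function(panel, spec, years = 2017:2030) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  stopifnot(inherits(spec, "esf_scenario"))
  check_columns(panel, c("muni_id", "year", "esf_coverage"), "panel")
  base <- panel %>%
    filter(.data$year == 2016) %>%
    arrange(.data$muni_id)
  if (nrow(base) == 0) abort("panel has no 2016 rows to anchor scenarios")
  cov16 <- base$esf_coverage
  n <- nrow(base)
  ny <- length(years)

  traj <- switch(spec$name,
    status_quo = outer(cov16, rep(1, ny)),
    uhc = {
      span <- spec$target_year - 2016
      frac <- pmin((years - 2016) / span, 1)
      outer(cov16, rep(1, ny)) + outer(1 - cov16, frac)
    },
    austerity = {
      if (is.null(spec$decline_path)) abort("austerity scenario requires a decline path")
      fac <- path_factor(spec$decline_path, years)
      outer(cov16, rep(1, ny)) * rep(fac, each = n)
    },
    austerity_mmp_end = {
      if (is.null(spec$decline_path)) abort("austerity scenario requires a decline path")
      check_columns(base, c("population", "mmp_doctors"), "panel (2016 rows)")
      fac <- path_factor(spec$decline_path, years)
      mmp <- mmp_coverage_contribution(base$mmp_doctors, base$population,
                                       total_coverage = cov16)
      residual <- cov16 - mmp
      full <- outer(cov16, rep(1, ny)) * rep(fac, each = n)
      cut <- outer(residual, rep(1, ny)) * rep(fac, each = n)
      after <- years >= spec$mmp_termination_year
      full[, after] <- cut[, after, drop = FALSE]
      full
    }
  )
  tibble(
    muni_id = rep(base$muni_id, times = ny),
    year = rep(years, each = n),
    scenario = spec$name,
    esf_coverage = clip(as.vector(traj), 0, 1)
  ) %>% arrange(.data$muni_id, .data$year)
}

path_factor <- function(path, years) {
  check_columns(path, c("year", "factor"), "decline path")
  f <- stats::approx(path$year, path$factor, xout = years, rule = 2)$y
  f
}

#' Coverage trajectories for every scenario
#'
#' Observed coverage up to 2016 is shared by all scenarios; 2017-2030
#' follows each scenario rule.
#'
#' @inheritParams apply_scenario
#' @param specs Named list of [scenario_spec()]s, default all four with
#'   default settings.
#' @param from First trajectory year (default 2010).
#' @return Tibble `muni_id`, `year`, `scenario`, `esf_coverage` covering
#'   `from`-2030 for each scenario.
#' @export
scenario_trajectories <- function(panel,
                                  specs = lapply(esf_scenarios(), scenario_spec),
                                  years = 2017:2030, from = 2010) {
  observed <- panel %>%
    filter(.data$year >= from, .data$year <= 2016) %>%
    select("muni_id", "year", "esf_coverage")
  bind_rows(lapply(specs, function(sp) {
    if (is.character(sp)) sp <- scenario_spec(sp)
    bind_rows(
      observed %>% mutate(scenario = sp$name),
      apply_scenario(panel, sp, years)
    )
  })) %>%
    select("muni_id", "year", "scenario", "esf_coverage") %>%
    arrange(.data$scenario, .data$muni_id, .data$year)
}
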