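## Configuration and end-to-end pipeline.
##
## A single nested configuration drives the whole analysis: synthetic
## generation (or a supplied panel CSV), covariate forecasting, national
## poverty calibration, scenario construction, Monte Carlo simulation and
## the summary tables. One master seed spawns deterministic per-stage
## substreams, so a rerun with the same configuration reproduces every
## output byte-identically.

#' Default pipeline configuration
#'
#' Desk-scale defaults: a 500-municipality synthetic cohort, 500 Monte
#' Carlo draws, the calibrated austerity decline path, Mais Medicos
#' termination in 2019 and the overall-ACSC outcome stratum.
#' @export
default_config <- function() {
  list(
    master_seed = 1L,
    panel_path = NULL,
    generator = list(
      n_municipalities = 500L,
      master_seed = 20301L
    ),
    effects = list(
      duration_lag = 4,
      quintile_multipliers = c(1, 1, 1, 1, 1),
      gamma = -0.022,
      gamma_shift = 0
    ),
    scenarios = list(
      decline_severity = 1,
      mmp_termination_year = 2019
    ),
    model = list(parameterization = "continuous"),
    simulation = list(
      n_draws = 500L,
      sample_effects = TRUE,
      sample_baseline = TRUE,
      effect_scale = "log",
      strata = "acsc_total"
    ),
    calibration = list(
      poverty_path = "default",
      observed_series = NULL,
      undernotification = 1
    ),
    output = list(directory = NULL)
  )
}

config_schema <- function() {
  list(
    master_seed = NULL, panel_path = NULL,
    generator = c("n_municipalities", "master_seed", "years",
                  "coverage_mean_2016", "coverage_sd_2016",
                  "mmp_strength", "mmp_doctors_per_capita",
                  "mmp_start_year", "traj_noise_sd", "alpha_sd",
                  "baseline_rates", "race_mix_mean", "race_mix_sd"),
    effects = c("duration_lag", "quintile_multipliers", "gamma",
                "gamma_shift", "strata", "covariates"),
    scenarios = c("decline_severity", "mmp_termination_year",
                  "decline_anchors"),
    model = c("parameterization"),
    simulation = c("n_draws", "sample_effects", "sample_baseline",
                   "effect_scale", "strata"),
    calibration = c("poverty_path", "observed_series", "undernotification"),
    output = c("directory")
  )
}

#' Merge configuration overrides into a base configuration
#'
#' Recursive merge; unknown keys are rejected by [validate_config()] when
#' the result is used.
#' @param base,overrides Nested configuration lists.
#' @export
merge_config <- function(base, overrides) {
  if (is.null(overrides)) return(base)
  modifyList(base, overrides)
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys (naming the offending key),
#' enforces the exclusivity of `panel_path` and `generator`, and checks
#' effect-size CIs through the [effect_table()] constructor.
#'
#' @param config Nested configuration list.
#' @return The validated configuration with defaults filled in.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key: %s", unknown[1]))
  }
  for (sec in names(schema)) {
    if (is.null(schema[[sec]]) || is.null(config[[sec]])) next
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad) > 0) {
      abort(sprintf("unknown configuration key: %s.%s", sec, bad[1]))
    }
  }
  explicit_generator <- !is.null(config$generator) &&
    length(config$generator) > 0
  cfg <- merge_config(default_config(), config)
  if (!is.null(cfg$panel_path)) {
    if (explicit_generator) {
      abort("configuration must name either panel_path or generator parameters, not both")
    }
    if (!file.exists(cfg$panel_path)) {
      abort(sprintf("panel file not found: %s", cfg$panel_path))
    }
    cfg$generator <- NULL
  }
  if (!is.numeric(cfg$master_seed) ||
      cfg$master_seed != as.integer(cfg$master_seed)) {
    abort("master_seed must be an integer")
  }
  # materialising the effect table validates rr CIs (lo <= point <= hi)
  build_effect_table(cfg)
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML configuration.
#' @return A validated configuration list with defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("configuration file not found: %s", path))
  validate_config(yaml::read_yaml(path))
}

build_effect_table <- function(cfg, include_gamma_shift = TRUE) {
  ec <- cfg$effects
  tb <- default_effect_table(
    duration_lag = ec$duration_lag,
    quintile_multipliers = unlist(ec$quintile_multipliers)
  )
  if (!is.null(ec$strata)) {
    st <- bind_rows(lapply(ec$strata, as_tibble))
    check_columns(st, c("stratum", "rr_full", "lo", "hi", "gamma"),
                  "effects.strata")
    tb <- effect_table(st, tb$covariates, duration_lag = ec$duration_lag,
                       quintile_multipliers = unlist(ec$quintile_multipliers))
  }
  if (!is.null(ec$covariates)) {
    cv <- bind_rows(lapply(ec$covariates, as_tibble))
    tb <- effect_table(tb$strata, cv, duration_lag = ec$duration_lag,
                       quintile_multipliers = unlist(ec$quintile_multipliers))
  }
  if (!is.null(ec$gamma)) tb$strata$gamma <- ec$gamma
  if (include_gamma_shift && !is.null(ec$gamma_shift) &&
      ec$gamma_shift != 0) {
    tb$strata$gamma <- tb$strata$gamma + ec$gamma_shift
  }
  tb
}

#' Run the full pipeline
#'
#' Generate (or load) the panel, forecast covariates to 2030, calibrate
#' national poverty, build scenario trajectories, run the Monte Carlo
#' simulation and produce the summary tables. When `config$output$directory`
#' is set the outputs are written as tidy CSVs with a JSON run manifest.
#'
#' @param config Configuration list (validated on entry).
#' @return A bundle list: `panel`, `trajectories`, `simulation`,
#'   `rates` (scenario/year summaries), `ratios`, `excess`,
#'   `quintile_rd`, `srr` (when race strata are simulated), `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- validate_config(config)
  table <- build_effect_table(cfg)
  strata <- unlist(cfg$simulation$strata)

  # --- cohort ---
  # the generating truth excludes sensitivity shifts of the prediction
  # trend, so trend variants alter the model, not the synthetic world
  if (!is.null(cfg$panel_path)) {
    panel <- read_panel(cfg$panel_path)
  } else {
    gen_table <- build_effect_table(cfg, include_gamma_shift = FALSE)
    gp <- cfg$generator
    params <- cohort_params(
      n_municipalities = gp$n_municipalities,
      master_seed = gp$master_seed %||% substream(cfg$master_seed, "generator"),
      true_effects = gen_table
    )
    for (nm in setdiff(names(gp), c("n_municipalities", "master_seed"))) {
      params[[nm]] <- gp[[nm]]
    }
    panel <- generate_cohort(params) %>%
      assign_mmp_doctors(params) %>%
      generate_deaths(gen_table, params)
  }

  # --- forecast + national calibration ---
  panel_full <- forecast_covariates(panel)
  pv <- cfg$calibration$poverty_path
  if (!is.null(pv)) {
    path <- if (identical(pv, "default")) {
      default_poverty_path()
    } else if (is.character(pv)) {
      readr::read_csv(pv, show_col_types = FALSE)
    } else {
      as_tibble(pv)
    }
    panel_full <- calibrate_national(panel_full, path)
  }

  # --- secular-trend calibration (optional) ---
  if (!is.null(cfg$calibration$observed_series)) {
    obs <- cfg$calibration$observed_series
    obs <- if (is.character(obs)) readr::read_csv(obs, show_col_types = FALSE) else as_tibble(obs)
    cal <- calibrate_secular_trend(
      panel, table, obs,
      stratum = strata[1],
      undernotification = cfg$calibration$undernotification
    )
    table <- cal$table
  }

  # --- scenarios ---
  anchors <- cfg$scenarios$decline_anchors
  decline <- if (is.null(anchors)) {
    make_decline_path(severity = cfg$scenarios$decline_severity)
  } else {
    make_decline_path(setNames(unlist(anchors), names(anchors)),
                      severity = cfg$scenarios$decline_severity)
  }
  specs <- list(
    scenario_spec("status_quo"),
    scenario_spec("austerity", decline_path = decline),
    scenario_spec("austerity_mmp_end", decline_path = decline,
                  mmp_termination_year = cfg$scenarios$mmp_termination_year),
    scenario_spec("uhc")
  )
  trajectories <- scenario_trajectories(panel_full, specs)

  # --- simulation ---
  spec <- draw_spec(
    n_draws = cfg$simulation$n_draws,
    master_seed = substream(cfg$master_seed, "simulation"),
    sample_effects = cfg$simulation$sample_effects,
    sample_baseline = cfg$simulation$sample_baseline,
    effect_scale = cfg$simulation$effect_scale
  )
  sim <- run_simulation(panel_full, trajectories, table, spec,
                        strata = strata,
                        parameterization = cfg$model$parameterization)

  rates <- summarise_rates(sim)
  comparisons <- list(c("austerity", "status_quo"),
                      c("austerity_mmp_end", "status_quo"),
                      c("austerity_mmp_end", "uhc"))
  ratios <- bind_rows(lapply(comparisons, function(cmp) {
    scenario_ratio(sim, cmp[1], cmp[2], years = c(2020, 2030))
  }))
  excess <- bind_rows(lapply(comparisons, function(cmp) {
    excess_deaths(sim, cmp[1], cmp[2], years = 2017:2030)
  }))
  quintile_rd <- if (!is.null(sim$quintile_draws)) {
    bind_rows(
      quintile_rate_difference(sim, "austerity", "status_quo"),
      quintile_rate_difference(sim, "austerity_mmp_end", "status_quo")
    )
  } else {
    NULL
  }
  srr <- if (all(c("acsc_black", "acsc_white") %in% strata)) {
    standardised_rate_ratio(sim, years = c(2020, 2030))
  } else {
    NULL
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("esfsim")),
    master_seed = cfg$master_seed,
    config_hash = rlang::hash(cfg),
    n_draws = cfg$simulation$n_draws,
    strata = strata,
    scenarios = esf_scenarios()
  )
  bundle <- list(panel = panel_full, trajectories = trajectories,
                 simulation = sim, rates = rates, ratios = ratios,
                 excess = excess, quintile_rd = quintile_rd, srr = srr,
                 manifest = manifest)

  out_dir <- cfg$output$directory
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a municipal panel from tidy CSV
#'
#' Expected columns: `muni_id`, `year`, `population`, the model
#' covariates, `esf_coverage`, `mmp_doctors` and optional
#' `deaths_<stratum>` columns.
#' @param path CSV path.
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(panel, c("muni_id", "year", "population", "esf_coverage"),
                "panel CSV")
  dup <- panel %>% dplyr::count(.data$muni_id, .data$year) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) abort("panel has duplicated (muni_id, year) rows")
  panel
}

#' Write a municipal panel as tidy CSV
#' @param panel Panel tibble.
#' @param path Destination path.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

write_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(bundle$rates, file.path(out_dir, "rates_by_scenario.csv"))
  readr::write_csv(bundle$ratios, file.path(out_dir, "scenario_ratios.csv"))
  readr::write_csv(bundle$excess, file.path(out_dir, "excess_deaths.csv"))
  readr::write_csv(bundle$trajectories, file.path(out_dir, "coverage_trajectories.csv"))
  if (!is.null(bundle$quintile_rd)) {
    readr::write_csv(bundle$quintile_rd, file.path(out_dir, "quintile_rate_differences.csv"))
  }
  if (!is.null(bundle$srr)) {
    readr::write_csv(bundle$srr, file.path(out_dir, "standardised_rate_ratios.csv"))
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
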