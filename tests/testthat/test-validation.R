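test_that("the concentrated FE Poisson fitter equals the dummy-variable glm", {
  set.seed(303)
  n_g <- 6
  n_t <- 8
  g <- rep(sprintf("G%02d", 1:n_g), each = n_t)
  X <- cbind(x1 = rnorm(n_g * n_t), x2 = runif(n_g * n_t))
  off <- log(runif(n_g * n_t, 500, 5000))
  eta <- rep(rnorm(n_g, 0, 0.5), each = n_t) + X %*% c(0.3, -0.5) + off
  d <- rpois(n_g * n_t, exp(eta - 5))
  off <- off - 5

  fit <- fit_fe_poisson(X, d, off, g)
  ref <- glm(d ~ x1 + x2 + factor(g), offset = off,
             family = poisson(),
             data = data.frame(d = d, X, g = g, off = off))
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients),
               unname(coef(ref)[c("x1", "x2")]), tolerance = 1e-6)
  expect_equal(fit$loglik,
               as.numeric(logLik(ref)) + sum(lfactorial(d)),
               tolerance = 1e-6)
})

test_that("secular-trend calibration recovers, fixes and shifts gamma correctly", {
  tab <- unit_effect_table(gamma = -0.022)
  panel <- flat_panel(n_muni = 10, years = 2000:2016, coverage = 0)
  prm <- flat_params(c(acsc_total = 80), tab, n = 10)
  panel <- generate_deaths(panel, tab, prm, poisson = FALSE)

  # self-consistency: observed series produced by the model itself
  obs <- tibble(year = 2010:2015, rate = 80 * exp(-0.022 * (2010:2015 - 2010)))
  cal <- calibrate_secular_trend(panel, unit_effect_table(gamma = 0), obs)
  expect_equal(cal$gamma, -0.022, tolerance = 1e-6)

  # fixed point: calibrating twice changes nothing
  cal2 <- calibrate_secular_trend(panel, cal$table, obs)
  expect_lt(abs(cal2$gamma - cal$gamma), 1e-6)

  # observed declining 2%/yr against a flat model
  obs98 <- tibble(year = 2010:2015, rate = 80 * 0.98^(2010:2015 - 2010))
  cal3 <- calibrate_secular_trend(panel, unit_effect_table(gamma = 0), obs98)
  expect_equal(cal3$gamma, log(0.98), tolerance = 1e-5)

  # undernotification scales the target series up before fitting
  cal4 <- calibrate_secular_trend(panel, unit_effect_table(gamma = 0),
                                  obs98, undernotification = 1.1)
  expect_equal(cal4$gamma, log(0.98), tolerance = 1e-5)

  expect_error(calibrate_secular_trend(panel, tab, obs98[1, ]), ">= 2")
  expect_error(
    calibrate_secular_trend(panel, tab, obs98 %>% mutate(rate = -rate)),
    "positive"
  )
})

test_that("internal validation recovers every input coefficient", {
  tab <- default_effect_table()
  pd <- scenario_death_panel(100, "austerity", tab, poisson = FALSE)
  iv <- internal_validation(pd, tab, "acsc_total", years = 2017:2030)
  expect_lt(iv$max_abs_dev, 1e-6)
  expect_true(iv$fit$converged)

  # a truly null covariate is fitted near zero under Poisson noise
  tab0 <- default_effect_table()
  tab0$covariates$rr[tab0$covariates$covariate == "public_beds"] <- 1
  devs <- sapply(1:20, function(r) {
    pd <- scenario_death_panel(60, "austerity", tab0, poisson = TRUE,
                               deaths_seed = 7000 + r)
    iv <- internal_validation(pd, tab0, "acsc_total", years = 2017:2030)
    row <- iv$report[iv$report$term == "public_beds", ]
    (row$estimate - 0) / row$std.error
  })
  expect_lt(abs(mean(devs)), 3 / sqrt(20) + 0.5)
})

test_that("constant-coverage panels are flagged as unidentifiable", {
  tab <- default_effect_table()
  pd <- scenario_death_panel(40, "status_quo", tab, poisson = FALSE)
  expect_error(internal_validation(pd, tab, "acsc_total"), "collinear")
})

test_that("external validation reports the regression of observed on predicted", {
  pred <- tibble(year = 2010:2015, rate = c(80, 78, 76, 75, 73, 71),
                 ci_lo = c(80, 78, 76, 75, 73, 71) - 3,
                 ci_hi = c(80, 78, 76, 75, 73, 71) + 3)
  # exact collinearity makes summary.lm warn about a perfect fit
  idn <- suppressWarnings(external_validation(pred, pred %>% select(year, rate)))
  expect_equal(idn$slope, 1)
  expect_equal(idn$intercept, 0, tolerance = 1e-10)
  expect_equal(idn$r_squared, 1)
  expect_equal(idn$frac_in_ci, 1)

  dbl <- suppressWarnings(
    external_validation(pred, pred %>% mutate(rate = 2 * rate) %>%
                          select(year, rate))
  )
  expect_equal(dbl$slope, 2)
  expect_equal(dbl$r_squared, 1)
  expect_equal(dbl$frac_in_ci, 0)

  expect_warning(
    short <- external_validation(pred[1:2, ], pred[1:2, ] %>%
                                   select(year, rate)),
    "fewer than 3"
  )
  expect_true(short$flagged)
  expect_true(is.na(short$r_squared))
  expect_error(external_validation(pred, tibble(year = 1990, rate = 1)),
               "overlapping")
})

test_that("sensitivity axes obey dose-response and trend-invariance", {
  cfg <- default_config()
  cfg$generator$n_municipalities <- 60L
  cfg$simulation$n_draws <- 1L
  cfg$simulation$sample_effects <- FALSE
  cfg$simulation$sample_baseline <- FALSE

  sens <- run_sensitivity(cfg, list(
    axis = "decline_magnitude",
    variants = list(
      mild = list(scenarios = list(decline_severity = 0.5)),
      base = list(scenarios = list(decline_severity = 1.0)),
      severe = list(scenarios = list(decline_severity = 1.5))
    )
  ))
  expect_true(all(diff(sens$ratio_austerity) > 0))
  expect_true(all(diff(sens$excess_austerity) > 0))
  expect_true(attr(sens, "dose_response_ok"))

  trend <- run_sensitivity(cfg, list(
    axis = "secular_trend",
    variants = list(
      slower = list(effects = list(gamma_shift = -0.01)),
      base = list(effects = list(gamma_shift = 0)),
      faster = list(effects = list(gamma_shift = 0.01))
    )
  ))
  # common secular-trend shifts cancel from between-scenario rate ratios
  expect_equal(trend$ratio_austerity,
               rep(trend$ratio_austerity[2], 3), tolerance = 1e-10)
  expect_equal(trend$ratio_austerity_mmp_end,
               rep(trend$ratio_austerity_mmp_end[2], 3), tolerance = 1e-10)

  expect_error(run_sensitivity(cfg, list(axis = "decline_magnitude",
                                         variants = list(list()))),
               ">= 2")
  expect_error(run_sensitivity(cfg, list(axis = "bogus",
                                         variants = list(a = list(), b = list()))),
               "unknown sensitivity axis")
})
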