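test_that("coverage effect interpolates the full-coverage anchors", {
  tab <- unit_effect_table()
  expect_equal(coverage_effect(1, 10, tab, "nutritional"), log(0.48))
  expect_equal(coverage_effect(0, 10, tab, "nutritional"), 0)
  expect_equal(coverage_effect(0.5, 10, tab, "nutritional"), 0.5 * log(0.48))
  # duration ramp: two of four lag years gives half the effect
  expect_equal(coverage_effect(1, 2, tab, "nutritional"), 0.5 * log(0.48))
  # categorical classes: none below 70%, half before consolidation, full after
  expect_equal(coverage_effect(0.6, 10, tab, "nutritional",
                               parameterization = "categorical"), 0)
  expect_equal(coverage_effect(0.9, 2, tab, "nutritional",
                               parameterization = "categorical"),
               0.5 * log(0.48))
  expect_equal(coverage_effect(0.9, 6, tab, "nutritional",
                               parameterization = "categorical"), log(0.48))
  expect_error(coverage_effect(1.2, 10, tab, "nutritional"), "\\[0, 1\\]")
  expect_error(coverage_effect(0.5, 10, tab, "no_such"), "unknown")
})

test_that("expected rates follow the log-linear model in closed form", {
  tab <- unit_effect_table()
  panel <- flat_panel(n_muni = 2, years = 2010, coverage = 0)
  fe <- c(T01 = log(50), T02 = log(50))
  expect_equal(expected_rate(panel, tab, "nutritional", fe, duration = c(0, 0)),
               c(50, 50))
  expect_equal(
    expected_rate(panel, tab, "nutritional", fe, coverage = c(1, 1),
                  duration = c(10, 10)),
    c(24, 24)
  )
  tabg <- unit_effect_table(gamma = -0.02)
  p2020 <- flat_panel(n_muni = 2, years = 2020, coverage = 0)
  expect_equal(
    expected_rate(p2020, tabg, "nutritional", fe, duration = c(0, 0)),
    rep(50 * exp(-0.2), 2),
    tolerance = 1e-12
  )
  expect_error(
    expected_rate(p2020 %>% select(-poverty_rate), tab, "nutritional", fe,
                  duration = c(0, 0)),
    "poverty_rate"
  )
})

test_that("rates are monotone non-increasing in coverage when rr_full < 1", {
  tab <- default_effect_table()
  set.seed(88)
  panel <- flat_panel(n_muni = 1, years = 2015)
  panel[esf_covariates()] <- as.list(rnorm(8, 0, 0.3))
  fe <- c(T01 = log(80))
  for (k in 1:50) {
    c1 <- runif(1)
    c2 <- runif(1, c1, 1)
    dur <- runif(1, 0, 12)
    r1 <- expected_rate(panel, tab, "acsc_total", fe, coverage = c1,
                        duration = dur)
    r2 <- expected_rate(panel, tab, "acsc_total", fe, coverage = c2,
                        duration = dur)
    expect_lte(r2, r1)
  }
})

test_that("fixed effects are recovered exactly from noise-free panels", {
  tab <- default_effect_table()
  sc <- small_cohort(50, seed = 23L)
  pd <- generate_deaths(sc$panel, tab, sc$params, poisson = FALSE)
  truth <- attr(pd, "true_alpha") %>% filter(stratum == "acsc_total")
  fe <- estimate_fixed_effects(pd, tab, "acsc_total")
  j <- dplyr::inner_join(truth, fe, by = "muni_id",
                         suffix = c("_true", "_fit"))
  expect_equal(nrow(j), 50)
  expect_lt(max(abs(j$alpha_true - j$alpha_fit)), 1e-8)
  expect_false(any(fe$flagged))
})

test_that("all-zero death histories anchor at the continuity floor, flagged", {
  tab <- unit_effect_table()
  panel <- flat_panel(n_muni = 2, years = 2010:2016, population = 1000,
                      coverage = 0)
  panel$deaths_acsc_total <- 0L
  fe <- estimate_fixed_effects(panel, tab, "acsc_total")
  expect_true(all(fe$flagged))
  # 0.5 deaths per 1000 person-years = 50 per 100,000
  expect_equal(fe$alpha, rep(log(50), 2))
})

test_that("fixed-effect anchoring is unbiased under Poisson noise", {
  tab <- unit_effect_table()
  panel <- flat_panel(n_muni = 20, years = 2010:2016, population = 5e5,
                      coverage = 0)
  prm <- flat_params(c(acsc_total = 80), tab, n = 20)
  est <- sapply(1:200, function(r) {
    pd <- generate_deaths(panel, tab, prm, seed = 6000 + r)
    estimate_fixed_effects(pd, tab, "acsc_total")$alpha
  })
  # log-scale anchoring carries the Jensen bias of E[log Poisson(mu)],
  # about -1/(2*mu); at mu = 400 expected deaths this bounds the bias
  mu <- 80 * 5e5 / 1e5
  bias <- mean(est) - log(80)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(bias), 1 / mu + 3 * se)
})

test_that("panel predictions have the contracted shape and scale consistency", {
  tab <- unit_effect_table()
  panel <- flat_panel(n_muni = 3, years = 2000:2030, coverage = 0.8)
  fe <- tibble(muni_id = sprintf("T%02d", 1:3), stratum = "acsc_total",
               alpha = log(60))
  tr <- scenario_trajectories(panel)
  pred <- predict_panel(panel, tr, fe, tab, strata = "acsc_total")
  expect_equal(nrow(pred), 3 * length(2010:2030) * 4)

  # identical trajectories => identical predictions
  sq <- tr %>% filter(scenario == "status_quo")
  sq2 <- sq %>% mutate(scenario = "clone")
  p2 <- predict_panel(panel, bind_rows(sq, sq2), fe, tab,
                      strata = "acsc_total")
  w <- p2 %>% tidyr::pivot_wider(names_from = scenario, values_from = rate)
  expect_equal(w$clone, w$status_quo)

  # rates are invariant to population scale
  big <- panel %>% mutate(population = population * 10)
  p3 <- predict_panel(big, tr, fe, tab, strata = "acsc_total")
  expect_equal(p3$rate, pred$rate)

  # frozen coverage and covariates: year-on-year ratio is exp(gamma)
  tabg <- unit_effect_table(gamma = -0.03)
  p4 <- predict_panel(panel, sq, fe, tabg, strata = "acsc_total") %>%
    filter(muni_id == "T01") %>% arrange(year)
  expect_equal(p4$rate[-1] / p4$rate[-nrow(p4)],
               rep(exp(-0.03), nrow(p4) - 1), tolerance = 1e-12)

  expect_error(
    predict_panel(panel, tr %>% mutate(muni_id = paste0("X", muni_id)),
                  fe, tab),
    "absent from panel"
  )
})
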