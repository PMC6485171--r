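test_that("effect-size sampling matches its CI-calibrated distribution", {
  tab <- effect_table(
    tibble(stratum = "acsc_total", rr_full = 0.49, lo = 0.40, hi = 0.60,
           gamma = 0),
    tibble(covariate = esf_covariates(), rr = 1, lo = 1, hi = 1)
  )
  d <- draw_effects(tab, n = 4000, seed = 101)
  rr <- d$rr[d$type == "rr_full"]
  sigma <- (log(0.60) - log(0.40)) / (2 * 1.96)
  expect_equal(sigma, 0.1034350, tolerance = 1e-6)
  s_hat <- sd(log(rr))
  expect_lt(abs(s_hat - sigma), 3 * sigma / sqrt(2 * 4000))
  expect_lt(abs(mean(log(rr)) - log(0.49)), 3 * sigma / sqrt(4000))
  # unit covariate CIs are degenerate: constant draws
  expect_true(all(d$rr[d$type == "covariate"] == 1))
  expect_true(all(d$rr > 0))
  # lo > hi is rejected at construction
  expect_error(effect_table(
    tibble(stratum = "a", rr_full = 0.5, lo = 0.6, hi = 0.4, gamma = 0),
    tibble(covariate = "x", rr = 1, lo = 1, hi = 1)
  ), "lo <= point <= hi")
})

make_two_muni_sim <- function(coverage_a = 0, coverage_b = 1,
                              stratum = "nutritional", n_draws = 1,
                              sample = FALSE, gamma = 0, seed = 1L,
                              keep_rates = TRUE) {
  tab <- unit_effect_table(gamma = gamma)
  panel <- flat_panel(n_muni = 2, years = 2000:2030, coverage = 1)
  prm <- flat_params(setNames(50, stratum), tab)
  panel <- generate_deaths(panel, tab, prm, poisson = FALSE)
  years <- 2010:2030
  traj <- bind_rows(
    tidyr::expand_grid(muni_id = c("T01", "T02"), year = years) %>%
      mutate(scenario = "a", esf_coverage = coverage_a),
    tidyr::expand_grid(muni_id = c("T01", "T02"), year = years) %>%
      mutate(scenario = "b", esf_coverage = coverage_b)
  )
  sim <- run_simulation(panel, traj, tab,
                        draw_spec(n_draws = n_draws, master_seed = seed,
                                  sample_effects = sample,
                                  sample_baseline = sample),
                        strata = stratum, keep_rates = keep_rates)
  list(sim = sim, panel = panel, traj = traj, tab = tab)
}

test_that("with sampling disabled the engine equals the deterministic model", {
  x <- make_two_muni_sim()
  fe <- estimate_fixed_effects(x$panel, x$tab, "nutritional")
  pred <- predict_panel(x$panel, x$traj, fe, x$tab, strata = "nutritional")
  j <- dplyr::inner_join(
    x$sim$rates %>% select(muni_id, year, scenario, rate_sim = rate),
    pred %>% select(muni_id, year, scenario, rate_det = rate),
    by = c("muni_id", "year", "scenario")
  )
  expect_equal(nrow(j), 2 * 21 * 2)
  expect_equal(j$rate_sim, j$rate_det, tolerance = 1e-12)
})

test_that("simulation output is reproducible under a fixed seed", {
  sc <- small_cohort(30, seed = 19L)
  tab <- default_effect_table()
  pd <- generate_deaths(sc$panel, tab, sc$params)
  pf <- forecast_covariates(pd)
  tr <- scenario_trajectories(pf)
  s1 <- run_simulation(pf, tr, tab, draw_spec(n_draws = 10, master_seed = 99))
  s2 <- run_simulation(pf, tr, tab, draw_spec(n_draws = 10, master_seed = 99))
  expect_identical(s1$summary_draws, s2$summary_draws)
  s3 <- run_simulation(pf, tr, tab, draw_spec(n_draws = 10, master_seed = 100))
  expect_false(identical(s1$summary_draws$mean_rate,
                         s3$summary_draws$mean_rate))
})

test_that("scenario ratios obey self-identity, reciprocity and model algebra", {
  x <- make_two_muni_sim(coverage_a = 0, coverage_b = 1,
                         stratum = "nutritional", n_draws = 5, sample = TRUE,
                         keep_rates = FALSE)
  # zero-vs-full consolidated coverage: deterministic ratio 1/0.48
  det <- make_two_muni_sim(coverage_a = 0, coverage_b = 1)
  r <- scenario_ratio(det$sim, "a", "b", years = 2030)
  expect_equal(r$estimate, 1 / 0.48, tolerance = 1e-10)
  expect_equal(r$ci_hi - r$ci_lo, 0)

  self <- scenario_ratio(det$sim, "a", "a", years = 2030)
  expect_equal(self$estimate, 1)
  expect_equal(self$ci_lo, 1)

  # reciprocity holds draw by draw
  w <- x$sim$summary_draws %>%
    filter(year == 2030) %>%
    select(draw, scenario, mean_rate) %>%
    tidyr::pivot_wider(names_from = scenario, values_from = mean_rate)
  expect_equal((w$a / w$b) * (w$b / w$a), rep(1, nrow(w)), tolerance = 1e-12)
})

test_that("excess deaths are antisymmetric and match direct arithmetic", {
  det <- make_two_muni_sim(coverage_a = 0, coverage_b = 1,
                           stratum = "nutritional")
  # rates: a = 50, b = 24 per 100k on population 100,000
  ex <- excess_deaths(det$sim, "a", "b", years = 2017:2030)
  expect_equal(ex$estimate, (50 - 24) * 2 * 14, tolerance = 1e-9)
  ex_rev <- excess_deaths(det$sim, "b", "a", years = 2017:2030)
  expect_equal(ex$estimate, -ex_rev$estimate)
  one <- excess_deaths(det$sim, "a", "b", years = 2030)
  expect_equal(one$estimate, 26 * 2, tolerance = 1e-9)
  expect_equal(excess_deaths(det$sim, "a", "a")$estimate, 0)
})

test_that("rate summaries order credible bounds and collapse when degenerate", {
  det <- make_two_muni_sim(n_draws = 3)
  s <- summarise_rates(det$sim)
  expect_true(all(s$ci_lo <= s$ci_hi))
  expect_true(all(s$ci_hi - s$ci_lo == 0))  # sampling disabled

  sc <- small_cohort(30, seed = 19L)
  tab <- default_effect_table()
  pd <- generate_deaths(sc$panel, tab, sc$params)
  pf <- forecast_covariates(pd)
  tr <- scenario_trajectories(pf)
  sim <- run_simulation(pf, tr, tab, draw_spec(n_draws = 20, master_seed = 1))
  s2 <- summarise_rates(sim)
  expect_true(all(s2$ci_lo <= s2$ci_hi))
  expect_true(all(s2$mean > 0))
  g <- glance(sim)
  expect_equal(g$n_draws, 20L)
  expect_equal(g$n_scenarios, 4L)
})
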