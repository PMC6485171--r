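test_that("poverty quintiles split evenly, break ties stably and stay fixed", {
  panel <- flat_panel(n_muni = 10, years = 2010:2012)
  panel$poverty_rate <- rep(seq(0.05, 0.5, length.out = 10),
                            each = 3)
  q <- quintile_stratify(panel)
  expect_equal(as.vector(base::table(q$quintile)), rep(2L, 5))
  # poorest municipalities (largest poverty) are quintile 1
  expect_equal(q$quintile[q$muni_id == "T10"], 1L)
  expect_equal(q$quintile[q$muni_id == "T01"], 5L)

  # later poverty changes do not move the assignment
  panel2 <- panel %>%
    mutate(poverty_rate = ifelse(year > 2010, 1 - poverty_rate, poverty_rate))
  expect_identical(quintile_stratify(panel2), q)

  # all-equal poverty: deterministic tie-broken 2/2/2/2/2 split by id
  panel3 <- panel %>% mutate(poverty_rate = 0.2)
  q3 <- quintile_stratify(panel3)
  expect_equal(as.vector(base::table(q3$quintile)), rep(2L, 5))
  expect_equal(q3$quintile[q3$muni_id == "T01"], 1L)

  expect_error(quintile_stratify(panel, baseline_year = 1990), "no rows")
})

test_that("concentration index matches its defining covariance formula", {
  # worked example: equal weights, rates 10..40 against ranks .125...875
  expect_equal(concentration_index(c(10, 20, 30, 40), c(4, 3, 2, 1)), 0.25)
  # no inequality
  expect_equal(concentration_index(rep(7, 5), 1:5), 0)
  # reversing the ranking flips the sign
  expect_equal(concentration_index(c(10, 20, 30, 40), c(1, 2, 3, 4)), -0.25)

  set.seed(202)
  for (k in 1:250) {
    n <- sample(2:25, 1)
    y <- runif(n, 0, 100)
    pov <- runif(n)
    w <- runif(n, 0.1, 10)
    ci <- concentration_index(y, pov, w)
    expect_lt(abs(ci - bf_concentration(y, pov, w)), 1e-12)
    expect_lte(abs(ci), 1)
  }
  expect_error(concentration_index(c(0, 0), c(1, 2)), "positive")
})

test_that("quintile rate differences vanish for identical scenarios and average consistently", {
  sc <- small_cohort(50, seed = 29L)
  tab <- default_effect_table()
  pd <- generate_deaths(sc$panel, tab, sc$params)
  pf <- forecast_covariates(pd)
  tr <- scenario_trajectories(pf)
  sim <- run_simulation(pf, tr, tab, draw_spec(n_draws = 5, master_seed = 4))

  rd0 <- quintile_rate_difference(sim, "austerity", "austerity")
  expect_true(all(rd0$estimate == 0))

  # municipality-count-weighted quintile means reproduce the overall mean
  qd <- sim$quintile_draws %>%
    filter(draw == 1, scenario == "austerity", year == 2030)
  counts <- base::table(quintile_stratify(pf)$quintile)
  overall <- sim$summary_draws %>%
    filter(draw == 1, scenario == "austerity", year == 2030)
  expect_equal(sum(qd$mean_rate * as.vector(counts)) / sum(counts),
               overall$mean_rate, tolerance = 1e-12)
})

test_that("standardised rate ratios follow stratum rate arithmetic", {
  tab <- unit_effect_table(rr_full = c(acsc_black = 1, acsc_white = 1))
  panel <- flat_panel(n_muni = 2, years = 2000:2030, coverage = 1)
  prm <- flat_params(c(acsc_black = 30, acsc_white = 20), tab)
  panel <- generate_deaths(panel, tab, prm, poisson = FALSE)
  traj <- tidyr::expand_grid(muni_id = c("T01", "T02"), year = 2010:2030) %>%
    mutate(scenario = "status_quo", esf_coverage = 1)
  sim <- run_simulation(panel, traj, tab,
                        draw_spec(n_draws = 1, sample_effects = FALSE,
                                  sample_baseline = FALSE),
                        strata = c("acsc_black", "acsc_white"))
  srr <- standardised_rate_ratio(sim, years = 2030)
  expect_equal(srr$estimate, 1.5, tolerance = 1e-10)

  # identical strata give SRR 1, and equal rr_full with identical
  # trajectories keeps the SRR constant over time
  tab2 <- unit_effect_table(rr_full = c(acsc_black = 0.8, acsc_white = 0.8))
  prm2 <- flat_params(c(acsc_black = 30, acsc_white = 30), tab2)
  panel2 <- generate_deaths(flat_panel(2, 2000:2030, coverage = 1),
                            tab2, prm2, poisson = FALSE)
  ramp <- tidyr::expand_grid(muni_id = c("T01", "T02"), year = 2010:2030) %>%
    mutate(scenario = "ramp",
           esf_coverage = pmin((year - 2009) / 21, 1))
  sim2 <- run_simulation(panel2, ramp, tab2,
                         draw_spec(n_draws = 1, sample_effects = FALSE,
                                   sample_baseline = FALSE),
                         strata = c("acsc_black", "acsc_white"))
  srr2 <- standardised_rate_ratio(sim2, years = 2010:2030,
                                  scenarios = "ramp")
  expect_equal(srr2$estimate, rep(1, 21), tolerance = 1e-10)
})

test_that("austerity increases racial and geographic inequality on the default cohort", {
  sc <- small_cohort(300, seed = 47L)
  tab <- default_effect_table()
  pd <- generate_deaths(sc$panel, tab, sc$params)
  pf <- forecast_covariates(pd) %>% calibrate_national(default_poverty_path())
  tr <- scenario_trajectories(pf)
  sim <- run_simulation(pf, tr, tab,
                        draw_spec(n_draws = 1, sample_effects = FALSE,
                                  sample_baseline = FALSE),
                        strata = c("acsc_total", "acsc_black", "acsc_white"))
  srr <- standardised_rate_ratio(sim, years = 2030)
  expect_gt(srr$estimate[srr$scenario == "austerity_mmp_end"],
            srr$estimate[srr$scenario == "status_quo"])
  expect_gt(srr$estimate[srr$scenario == "austerity"],
            srr$estimate[srr$scenario == "status_quo"])

  cc <- concentration_change(sim, "austerity_mmp_end", "status_quo",
                             years = 2030)
  expect_gt(cc$estimate, 0)

  rd <- quintile_rate_difference(sim, "austerity_mmp_end", "status_quo",
                                 years = 2030)
  expect_gt(rd$estimate[rd$quintile == 1], rd$estimate[rd$quintile == 5])
  expect_true(all(rd$estimate > 0))
})
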