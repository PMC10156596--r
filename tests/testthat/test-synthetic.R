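# Synthetic-data generators: forward-model correctness, invariants,
# determinism.

test_that("noise-free PAD curves lie exactly on the sigmoid", {
  # direct evaluation of 100 / (1 + exp((S/25)(psi - psi50)))
  expect_equal(pad_sigmoid(-3, -2, 50), 100 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(pad_sigmoid(-2, -2, 50), 50)
  expect_equal(pad_sigmoid(0, -2, 50), 100 / (1 + exp(4)), tolerance = 1e-12)

  cfg <- curve_sim_config(psi50_true = -2, slope_true = 50,
                          psi_grid = c(0, -1, -2, -3, -4), noise_sd = 0)
  cv <- gen_pad_curve(cfg)
  expect_equal(cv$pad, pad_sigmoid(cv$psi_mpa, -2, 50))
  expect_equal(cv$pad[3], 50)
})

test_that("PAD noise is clipped to [0, 100] and seeds are reproducible", {
  cfg <- curve_sim_config(psi50_true = -2, slope_true = 50, n_points = 30,
                          noise_sd = 40, seed = 3)
  a <- gen_pad_curve(cfg)
  b <- gen_pad_curve(cfg)
  expect_identical(a, b)
  expect_true(all(a$pad >= 0 & a$pad <= 100))
  cfg2 <- curve_sim_config(psi50_true = -2, slope_true = 50, n_points = 30,
                           noise_sd = 40, seed = 4)
  expect_false(identical(gen_pad_curve(cfg2), a))
})

test_that("a psi grid that misses the true psi50 warns", {
  cfg <- curve_sim_config(psi50_true = -5, slope_true = 50,
                          psi_grid = c(0, -0.5, -1, -1.5))
  expect_warning(gen_pad_curve(cfg), "one side")
})

test_that("simulated climate honours the configured dry season", {
  # no dry months: every month at or above 100 mm, DSL 0 downstream
  wet <- gen_climate(climate_sim_config(map_total = 2400, dry_months = 0,
                                        n_years = 3, seed = 1))
  expect_true(all(wet$precip_mm >= 100))
  expect_equal(dry_season_length(wet), 0)

  # 5 dry months at 60 mm: DSL 5 downstream, annual totals exact
  dry <- gen_climate(climate_sim_config(map_total = 2000, dry_months = 5,
                                        dry_month_precip = 60, n_years = 4,
                                        seed = 2))
  expect_equal(dry_season_length(dry), 5)
  expect_equal(as.numeric(tapply(dry$precip_mm, dry$year, sum)), rep(2000, 4))

  # 1200 mm over 12 equal months: exactly 100 mm each
  flat <- gen_climate(climate_sim_config(map_total = 1200, dry_months = 0,
                                         n_years = 1, seed = 1))
  expect_equal(flat$precip_mm, rep(100, 12))

  expect_error(climate_sim_config(map_total = 300, dry_months = 2,
                                  dry_month_precip = 160),
               "impossible configuration")
})

test_that("census generator obeys its demographic invariants", {
  # closed population: stem count constant
  closed <- gen_census(census_sim_config(n_trees0 = 100, n_censuses = 4,
                                         annual_mortality = 0,
                                         annual_recruitment = 0, seed = 5))
  counts <- tapply(closed$status %in% c("alive", "recruit"),
                   closed$census_date, sum)
  expect_true(all(counts == 100))

  # deterministic growth: every survivor gains exactly growth * interval
  fixed <- gen_census(census_sim_config(n_trees0 = 50, n_censuses = 2,
                                        interval_yr = 5, annual_mortality = 0,
                                        annual_recruitment = 0,
                                        dbh_growth_mean = 0.2,
                                        dbh_growth_sd = 0, seed = 6))
  d0 <- fixed[fixed$census_date == 2000, ]
  d1 <- fixed[fixed$census_date == 2005, ]
  expect_equal(d1$dbh[match(d0$tree_id, d1$tree_id)] - d0$dbh, rep(1.0, 50))

  # all DBH at or above the 10 cm census threshold
  noisy <- gen_census(census_sim_config(n_trees0 = 400, n_censuses = 3,
                                        annual_mortality = 0.05,
                                        annual_recruitment = 0.05, seed = 7))
  expect_true(all(noisy$dbh >= 10))

  # dead trees never reappear; survivor DBH non-decreasing
  by_tree <- split(noisy, noisy$tree_id)
  for (tr in by_tree) {
    tr <- tr[order(tr$census_date), ]
    if (any(tr$status == "dead")) {
      expect_equal(which(tr$status == "dead"), nrow(tr))
    }
    live_dbh <- tr$dbh[tr$status %in% c("alive", "recruit")]
    expect_true(all(diff(live_dbh) >= 0))
  }

  # identical seeds give identical tables
  cfg <- census_sim_config(n_trees0 = 200, seed = 8)
  expect_identical(gen_census(cfg), gen_census(cfg))
})

test_that("survival matches the exponential model within binomial bounds", {
  # m = 0.02/yr over 5 yr: expected survivors 1000 * exp(-0.1) ~ 905
  cen <- gen_census(census_sim_config(n_trees0 = 1000, n_censuses = 2,
                                      interval_yr = 5, annual_mortality = 0.02,
                                      annual_recruitment = 0, seed = 9))
  second <- cen[cen$census_date == 2005 & cen$status == "alive", ]
  p <- exp(-0.1)
  bounds <- qbinom(c(0.005, 0.995), 1000, p)
  expect_gte(nrow(second), bounds[1])
  expect_lte(nrow(second), bounds[2])
})

test_that("scenario coupling is exact in the noise-free limit", {
  scn <- gen_scenario(scenario_config(
    n_sites = 8, hsm_slope_true = 0.0025, hsm_noise_sd = 0,
    dynamics_coupling = 0.006, dagb_rel_base = 0.004, dyn_noise_sd = 0,
    annual_mortality = 0, annual_recruitment = 0, dbh_growth_sd = 0,
    n_trees0 = 300, seed = 21))
  tab <- scenario_site_table(scn)
  fit <- sma_fit(tab$hsm50, tab$dagb_rel, bootstrap_n = 0)
  expect_equal(fit$slope, 0.006, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  # realized CWM HSM50 from the pipeline matches the generator's ground truth
  expect_equal(sort(tab$hsm50), sort(scn$sites$cwm_hsm_true), tolerance = 1e-10)
})

test_that("noisy scenarios recover the coupling slope on average", {
  slopes <- vapply(1:40, function(s) {
    scn <- gen_scenario(scenario_config(seed = s, hsm_slope_true = 0,
                                        hsm_noise_sd = 0.6))
    tab <- scenario_site_table(scn)
    sma_fit(tab$hsm50, tab$dagb_rel, bootstrap_n = 0)$slope
  }, 0)
  # SMA slope magnitude inflates by 1/sqrt(r2) under residual noise, so the
  # mean sits slightly above the generating slope; 10% covers that
  expect_equal(mean(slopes), 0.01, tolerance = 0.1)
})

test_that("scenario climate reproduces the drawn water-deficit targets", {
  scn <- gen_scenario(scenario_config(n_sites = 6, seed = 31))
  cs <- climate_summary(scn$climate, e_mode = "top3")
  m <- merge(cs, scn$sites, by = "site")
  expect_equal(m$mcwd, m$mcwd_true, tolerance = 1e-9)
})
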