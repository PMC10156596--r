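# PAD normalization and sigmoid curve fitting.

test_that("air-discharge normalization is a linear map to [0, 100]", {
  s <- data.frame(psi_mpa = c(0, -1, -2), air_discharge = c(2, 6, 10))
  expect_equal(normalize_air_discharge(s)$pad, c(0, 50, 100))

  s2 <- data.frame(psi_mpa = c(0, -1, -2, -3),
                   air_discharge = c(5, 5.9, 9.5, 23))
  expect_equal(normalize_air_discharge(s2)$pad, c(0, 5, 25, 100))

  flat <- data.frame(psi_mpa = c(0, -1, -2), air_discharge = c(7, 7, 7))
  expect_error(normalize_air_discharge(flat), "flat discharge")
})

test_that("normalization is applied per branch and preserves order", {
  s <- rbind(data.frame(branch_id = "a", psi_mpa = c(0, -1, -2, -3),
                        air_discharge = c(1, 2, 3, 5)),
             data.frame(branch_id = "b", psi_mpa = c(0, -1, -2, -3),
                        air_discharge = c(10, 30, 40, 50)))
  out <- normalize_air_discharge(s)
  expect_equal(out$pad[1:4], c(0, 25, 50, 100))
  expect_equal(out$pad[5:8], c(0, 50, 75, 100))
  expect_identical(out$branch_id, s$branch_id)
})

test_that("noise-free curves are recovered to machine-level accuracy", {
  for (p50 in c(-6, -2, -0.8)) {
    for (s in c(25, 80)) {
      cv <- gen_pad_curve(curve_sim_config(psi50_true = p50, slope_true = s,
                                           n_points = 10))
      f <- fit_curve(cv, bootstrap_n = 0)
      expect_lt(abs(f$psi50 - p50), 1e-6)
      expect_lt(abs(f$slope_s - s), 1e-4)
      expect_lt(f$sse, 1e-10)
      expect_true(f$converged)
    }
  }
})

test_that("the optimizer matches the brute-force grid oracle on noisy data", {
  for (seed in c(42, 43, 44)) {
    cv <- gen_pad_curve(curve_sim_config(psi50_true = -2.4, slope_true = 60,
                                         n_points = 10, noise_sd = 5,
                                         seed = seed))
    f <- fit_curve(cv, bootstrap_n = 0)
    oracle <- grid_search_sse(cv$psi_mpa, cv$pad)
    expect_lte(f$sse, oracle$sse + 1e-6)
  }
})

test_that("fit invariants hold: monotone sigmoid, PAD 50 at psi50, Eq. 3 identity", {
  cv <- gen_pad_curve(curve_sim_config(psi50_true = -3, slope_true = 40,
                                       n_points = 12, noise_sd = 8, seed = 11))
  f <- fit_curve(cv, bootstrap_n = 0)
  expect_gt(f$slope_s, 0)
  grid <- seq(0, -8, by = -0.25)
  pred <- pad_sigmoid(grid, f$psi50, f$slope_s)
  expect_true(all(diff(pred) > 0))  # PAD rises as psi falls
  expect_equal(pad_sigmoid(f$psi50, f$psi50, f$slope_s), 50)
  expect_equal(f$psi50 - f$psi88, 50 / f$slope_s, tolerance = 1e-12)
})

test_that("fits are invariant to point order and raw-unit rescaling", {
  set.seed(2)
  raw <- data.frame(psi_mpa = seq(0, -6, length.out = 10),
                    air_discharge = sort(runif(10, 1, 40)))
  f1 <- fit_curve(normalize_air_discharge(raw), bootstrap_n = 0)
  shuffled <- raw[sample(nrow(raw)), ]
  f2 <- fit_curve(normalize_air_discharge(shuffled), bootstrap_n = 0)
  rescaled <- transform(raw, air_discharge = 3.7 * air_discharge + 12)
  f3 <- fit_curve(normalize_air_discharge(rescaled), bootstrap_n = 0)
  expect_equal(f1$psi50, f2$psi50, tolerance = 1e-8)
  expect_equal(f1$psi50, f3$psi50, tolerance = 1e-8)
  expect_equal(f1$slope_s, f3$slope_s, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_curve(data.frame(psi_mpa = c(0, -1, -2), pad = c(0, 50, 100))),
               "at least 4")
  expect_error(fit_curve(data.frame(psi_mpa = rep(-1, 5), pad = 1:5 * 10)),
               "span")
  expect_warning(
    fit_curve(data.frame(psi_mpa = c(0, -1, -2, -3, -4),
                         pad = c(-5, 20, 50, 90, 104)), bootstrap_n = 0),
    "clipped")
})

test_that("psi88 closed form matches its definition and the analytic inversion", {
  expect_equal(psi88_from_fit(-2, 25), -4)
  expect_equal(psi88_from_fit(-2, 50), -3)
  expect_error(psi88_from_fit(-2, 0), "slope_s")
  # numeric inversion of the sigmoid at PAD = 88 differs from the closed
  # form by exactly (2 - log(88/12)) * 25 / S
  for (s in c(10, 25, 50, 120, 300)) {
    inv <- uniroot(function(p) pad_sigmoid(p, -2, s) - 88, c(-40, 0),
                   tol = 1e-13)$root
    expect_equal(abs(psi88_from_fit(-2, s) - inv), (2 - log(88 / 12)) * 25 / s,
                 tolerance = 1e-7)
  }
})

test_that("bootstrap interval brackets the point estimate", {
  cv <- gen_pad_curve(curve_sim_config(psi50_true = -2, slope_true = 50,
                                       n_points = 10, noise_sd = 5, seed = 12))
  f <- fit_curve(cv, bootstrap_n = 200, seed = 99)
  expect_true(f$ci_psi50[1] <= f$psi50 && f$psi50 <= f$ci_psi50[2])
  expect_true(f$ci_slope[1] <= f$slope_s && f$slope_s <= f$ci_slope[2])
  # seeded bootstrap is reproducible
  f2 <- fit_curve(cv, bootstrap_n = 200, seed = 99)
  expect_identical(f$ci_psi50, f2$ci_psi50)
})

test_that("species-site aggregation strategies behave as documented", {
  one <- gen_pad_curve(curve_sim_config(psi50_true = -2, slope_true = 50,
                                        n_points = 10))
  one$branch_id <- "b1"
  f_single <- species_site_fit(one, strategy = "pooled")
  f_ref <- fit_curve(one, bootstrap_n = 0)
  expect_equal(f_single$psi50, f_ref$psi50)

  # two identical noise-free curves: strategies agree exactly
  two <- rbind(one, transform(one, branch_id = "b2"))
  fp <- species_site_fit(two, strategy = "pooled")
  fm <- species_site_fit(two, strategy = "mean_of_individuals")
  expect_equal(fp$psi50, fm$psi50, tolerance = 1e-8)

  # curves at -1 and -3: mean-of-individuals returns the arithmetic mean
  c1 <- gen_pad_curve(curve_sim_config(psi50_true = -1, slope_true = 50,
                                       psi_grid = seq(0, -6, length.out = 10)))
  c2 <- gen_pad_curve(curve_sim_config(psi50_true = -3, slope_true = 50,
                                       psi_grid = seq(0, -6, length.out = 10)))
  c1$branch_id <- "b1"; c2$branch_id <- "b2"
  fm2 <- species_site_fit(rbind(c1, c2), strategy = "mean_of_individuals")
  expect_equal(fm2$psi50, -2, tolerance = 1e-6)
  fp2 <- species_site_fit(rbind(c1, c2), strategy = "pooled")
  expect_false(isTRUE(all.equal(fp2$psi50, fm2$psi50, tolerance = 1e-4)))

  mixed <- rbind(transform(c1, species = "A"), transform(c2, species = "B"))
  expect_error(species_site_fit(mixed), "single species")
})
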