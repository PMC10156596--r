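# Census-based carbon dynamics: allometry, fluxes, rates, plot rules.

test_that("height and biomass allometry evaluate their closed forms", {
  cfg <- allometry_config(weibull_a = 40, weibull_b = 0.03, weibull_c = 1)
  expect_equal(tree_height(20, cfg), 40 * (1 - exp(-0.6)))
  expect_equal(tree_height(0, cfg), 0)
  expect_lt(tree_height(1e5, cfg), 40 + 1e-9)  # asymptote
  expect_true(all(diff(tree_height(seq(1, 120, by = 1))) > 0))

  expect_equal(tree_agb(20, 0.6, height = 25), 0.0509 * 0.6 * 400 * 25)
  expect_equal(tree_agb(20, 0.6, height = 25), 305.4)
  expect_equal(tree_agb(40, 0.6, height = 25), 4 * tree_agb(20, 0.6, height = 25))
  expect_equal(tree_agb(1, 1, height = 1), 0.0509)
})

test_that("plot biomass sums live trees and scales with area", {
  cen <- data.frame(tree_id = c("a", "b"), wood_density = 0.6,
                    dbh = 20, status = "alive")
  cfg25 <- allometry_config()
  # fix height at 25 m via a degenerate Weibull for a hand-checkable sum
  cfgH <- allometry_config(weibull_a = 25, weibull_b = 1e9, weibull_c = 1)
  expect_equal(plot_agb(cen, 1, cfgH), 2 * 305.4 / 1000)
  expect_equal(plot_agb(cen, 0.5, cfgH), 2 * 305.4 / 1000 / 0.5)
  expect_equal(plot_agb(cen[0, ], 1, cfg25), 0)
  expect_error(plot_agb(cen, 0), "plot_area")
})

test_that("net biomass change is the annualized stock difference", {
  expect_equal(delta_agb(300, 312, 10), 1.2)
  expect_equal(delta_agb(300, 300, 10), 0)
  expect_equal(delta_agb(312, 300, 10), -1.2)
  expect_error(delta_agb(300, 312, 0), "> 0")
})

# toy census: one survivor 100 -> 150 kg, one recruit at 20 kg, one death at
# 80 kg over 5 yr in 1 ha; heights fixed by a saturated Weibull so biomass
# values are exact
toy_cfg <- allometry_config(weibull_a = 25, weibull_b = 1e9, weibull_c = 1)
toy_census <- local({
  d100 <- dbh_for_agb(100, 0.6, toy_cfg); d150 <- dbh_for_agb(150, 0.6, toy_cfg)
  d20 <- dbh_for_agb(20, 0.6, toy_cfg); d80 <- dbh_for_agb(80, 0.6, toy_cfg)
  build_census(list(
    list(id = "s1", wd = 0.6, dbh = c(d100, d150), status = c("alive", "alive")),
    list(id = "r1", wd = 0.6, dbh = c(NA, d20), status = c(NA, "recruit")),
    list(id = "d1", wd = 0.6, dbh = c(d80, d80), status = c("alive", "dead"))),
    dates = c(2000, 2005))
})

test_that("production and mortality match the hand-computed toy census", {
  rules <- dynamics_rules(unobserved_recruits = FALSE)
  fx <- agwp(toy_census, plot_area = 1, cfg = toy_cfg, rules = rules)
  # components: survivor growth 50, recruit 20, unobserved recruits 0,
  # dying tree credited its half-interval share of the 10 kg/yr median
  # survivor growth = 25 kg
  expect_equal(fx$survivor_growth, 50 / 5 / 1000)
  expect_equal(fx$recruit_agb, 20 / 5 / 1000)
  expect_equal(fx$unobs_recruit_growth, 0)
  expect_equal(fx$unobs_dying_growth, 25 / 5 / 1000)
  expect_equal(fx$agwp, 0.019)
  expect_equal(fx$agb_mort, (80 + 25) / 5 / 1000)
  expect_equal(fx$agb_mort, 0.021)
  # net balance: (170 - 180)/1000/5
  expect_equal(fx$agb_end - fx$agb_start, (fx$agwp - fx$agb_mort) * 5)
})

test_that("the unobserved-recruit estimate follows its stated approximation", {
  fx <- agwp(toy_census, plot_area = 1, cfg = toy_cfg, rules = dynamics_rules())
  m <- (log(2) - log(1)) / 5
  n_unobs <- (1 / 5) * m * 25 / 2
  expect_equal(fx$unobs_recruit_growth,
               n_unobs * tree_agb(10, 0.6, cfg = toy_cfg) / 5 / 1000)
  # the same term is credited to mortality, so conservation still holds
  expect_equal(fx$agb_end - fx$agb_start, (fx$agwp - fx$agb_mort) * 5,
               tolerance = 1e-12)
})

test_that("unmatched non-recruit trees raise an error naming them", {
  bad <- rbind(toy_census,
               data.frame(plot_id = "toy", tree_id = "ghost", species = "sp1",
                          wood_density = 0.6, census_date = 2005, dbh = 30,
                          status = "alive"))
  expect_error(agwp(bad, plot_area = 1, cfg = toy_cfg), "ghost")
})

test_that("stem mortality follows the log-ratio form and its guards", {
  expect_equal(stem_mortality_rate(100, 100, 5), 0)
  expect_equal(stem_mortality_rate(100, 90, 2), log(100 / 90) / 2 * 100)
  expect_equal(stem_mortality_rate(100, 50, 1), log(2) * 100)
  # per-plot vs per-ha counts give the same rate
  expect_equal(stem_mortality_rate(100, 90, 2), stem_mortality_rate(50, 45, 2))
  expect_error(stem_mortality_rate(100, 0, 5), "> 0")
  expect_error(stem_mortality_rate(90, 100, 5), "exceed")
})

test_that("census-interval standardization scales by the interval ratio", {
  expect_equal(standardize_rate(5, 5, 5, 0.08), 5)
  expect_equal(standardize_rate(5, 5, 1, 0.08), 5 * 5^0.08)
  expect_equal(standardize_rate(5, 5, 1, 0), 5)
})

test_that("residence time is stock over flux with a guarded zero", {
  expect_equal(residence_time(300, 6), 50)
  expect_equal(residence_time(300, 300), 1)
  expect_warning(v <- residence_time(300, 0), "undefined")
  expect_true(is.na(v))
})

test_that("relative metrics divide by standing biomass and invert tau_w", {
  cen <- gen_census(census_sim_config(n_trees0 = 300, n_censuses = 3,
                                      interval_yr = 5, seed = 13))
  d <- plot_dynamics(cen, plot_area = 1)
  expect_equal(d$dagb_rel, d$dagb_abs / d$agb_tw_mean)
  expect_equal(d$agb_mort_rel, 1 / d$tau_w, tolerance = 1e-12)
  expect_equal(d$tau_w * d$agb_mort, d$agb_tw_mean, tolerance = 1e-9)
})

test_that("carbon balance conserves exactly on simulated and edge censuses", {
  for (seed in 1:5) {
    cen <- gen_census(census_sim_config(n_trees0 = 250, n_censuses = 4,
                                        interval_yr = 5,
                                        annual_mortality = 0.03,
                                        annual_recruitment = 0.04, seed = seed))
    d <- plot_dynamics(cen, plot_area = 1)
    expect_lt(abs(d$dagb_abs - (d$agwp - d$agb_mort)), 1e-9)
  }
  # every tree dies
  all_die <- build_census(list(
    list(id = "a", wd = 0.6, dbh = c(20, 20), status = c("alive", "dead")),
    list(id = "b", wd = 0.5, dbh = c(30, 30), status = c("alive", "dead"))),
    dates = c(2000, 2010))
  d2 <- plot_dynamics(all_die, plot_area = 1)
  expect_equal(d2$agwp, 0)
  expect_lt(abs(d2$dagb_abs - (d2$agwp - d2$agb_mort)), 1e-12)
  # nobody dies, nobody recruits
  none <- build_census(list(
    list(id = "a", wd = 0.6, dbh = c(20, 24), status = c("alive", "alive"))),
    dates = c(2000, 2010))
  d3 <- plot_dynamics(none, plot_area = 1)
  expect_equal(d3$agb_mort, 0)
  expect_equal(d3$agwp, d3$intervals$survivor_growth)
})

test_that("small neighbouring plots merge by connected components", {
  plots <- data.frame(
    plot_id = c("p1", "p2", "p3", "p4"),
    area_ha = c(0.25, 0.25, 0.25, 1.0),
    lat = c(-10.000, -10.0018, -9.95, -10.00),   # p1-p2 ~200 m apart
    lon = c(-60.000, -60.000, -60.000, -60.001))
  out <- merge_small_plots(plots)
  expect_equal(out$merged_id[1], out$merged_id[2])
  expect_equal(out$merged_area_ha[1], 0.5)
  expect_false(out$merged_id[3] == out$merged_id[1])  # ~5.5 km away
  expect_equal(out$merged_id[4], "p4")                # big plots never merge
  missing_xy <- data.frame(plot_id = "q", area_ha = 0.2,
                           lat = NA_real_, lon = NA_real_)
  expect_error(merge_small_plots(missing_xy), "coordinates")
})

test_that("census window selection applies the cutoffs and the rescue rule", {
  a <- select_censuses(c(1999, 2004, 2009, 2014))
  expect_equal(a$dates, c(2004, 2009, 2014))  # 10 yr without pre-2000 help
  expect_false(a$flagged)

  b <- select_censuses(c(1999, 2005, 2008))
  expect_equal(b$dates, c(1999, 2005, 2008))  # pre-2000 census admitted
  expect_true(b$flagged)                       # still short of 10 yr
  expect_false(b$excluded)

  c3 <- select_censuses(c(2003, 2016))
  expect_true(c3$excluded)
})
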