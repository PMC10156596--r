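# Seeded synthetic-data generators: vulnerability curves, monthly climate,
# birth-death-growth censuses, and coupled multi-site scenarios with known
# ground truth.

#' Configuration for a simulated vulnerability curve
#'
#' @param psi50_true true water potential at 50% air discharge (MPa, < 0).
#' @param slope_true true sigmoid slope (% MPa^-1, > 0).
#' @param n_points number of dehydration steps (>= 4); ignored when
#'   `psi_grid` is supplied.
#' @param psi_grid optional water potentials (MPa, descending from 0) at
#'   which PAD is observed; defaults to an even grid from 0 to twice
#'   `psi50_true`.
#' @param noise_sd additive Gaussian measurement noise on PAD (>= 0).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return A list of class `curve_sim_config`.
#' @export
curve_sim_config <- function(psi50_true = -2, slope_true = 50, n_points = 10,
                             psi_grid = NULL, noise_sd = 0, seed = 1) {
  check_number(psi50_true, "psi50_true", upper = 0, strict_upper = TRUE)
  check_number(slope_true, "slope_true", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (is.null(psi_grid)) {
    psi_grid <- seq(0, 2 * psi50_true, length.out = n_points)
  }
  if (length(psi_grid) < 4) abort("psi_grid needs at least 4 points")
  structure(list(psi50_true = psi50_true, slope_true = slope_true,
                 n_points = length(psi_grid), psi_grid = psi_grid,
                 noise_sd = noise_sd, seed = seed),
            class = "curve_sim_config")
}

#' Simulate a PAD vulnerability curve
#'
#' Forward-evaluates the sigmoid [pad_sigmoid()] on the configured water
#' potential grid and adds Gaussian noise clipped to [0, 100]. With zero
#' noise the points lie exactly on the sigmoid, so the curve fitter must
#' recover the true parameters. Clipping slightly biases points near the
#' bounds; that is intentional, since real PAD data are bounded percentages.
#'
#' @param cfg a [curve_sim_config()].
#' @return Data frame with columns `branch_id`, `psi_mpa`, `pad`.
#' @export
gen_pad_curve <- function(cfg) {
  stopifnot(inherits(cfg, "curve_sim_config"))
  if (min(cfg$psi_grid) > cfg$psi50_true || max(cfg$psi_grid) < cfg$psi50_true) {
    warnf("psi_grid lies entirely on one side of psi50_true; recovery will be poor")
  }
  pad <- pad_sigmoid(cfg$psi_grid, cfg$psi50_true, cfg$slope_true)
  if (cfg$noise_sd > 0) {
    pad <- with_seed(cfg$seed, pad + stats::rnorm(length(pad), 0, cfg$noise_sd))
    pad <- pmin(pmax(pad, 0), 100)
  }
  data.frame(branch_id = "sim", psi_mpa = cfg$psi_grid, pad = pad)
}

#' Configuration for a simulated monthly climate series
#'
#' Emulates a seasonal tropical rainfall regime: a contiguous mid-year dry
#' season of `dry_months` months at `dry_month_precip` mm each, with the
#' remaining annual total spread evenly over the wet months.
#'
#' @param map_total mean annual precipitation (mm yr^-1).
#' @param dry_months number of dry months per year (0-12).
#' @param dry_month_precip precipitation of each dry month (mm, < 100 for a
#'   climatological dry season).
#' @param et_monthly monthly evapotranspiration written to the table (mm).
#' @param n_years number of years to generate.
#' @param jitter_sd Gaussian jitter on monthly totals (mm; dry months stay
#'   below 100 mm and wet months at or above 100 mm when so configured).
#' @param seed RNG seed.
#' @return A list of class `climate_sim_config`.
#' @export
climate_sim_config <- function(map_total = 2200, dry_months = 4,
                               dry_month_precip = 60, et_monthly = 100,
                               n_years = 10, jitter_sd = 0, seed = 1) {
  check_number(dry_months, "dry_months", lower = 0, upper = 12)
  check_number(dry_month_precip, "dry_month_precip", lower = 0)
  check_number(map_total, "map_total", lower = 0)
  wet_months <- 12 - dry_months
  if (wet_months > 0) {
    wet <- (map_total - dry_months * dry_month_precip) / wet_months
    if (wet < 0) {
      abort("impossible configuration: implied wet-month precipitation %.1f mm < 0", wet)
    }
    if (dry_months > 0 && wet < 100) {
      warnf("implied wet-month precipitation %.1f mm is itself below 100 mm", wet)
    }
  }
  structure(list(map_total = map_total, dry_months = dry_months,
                 dry_month_precip = dry_month_precip, et_monthly = et_monthly,
                 n_years = n_years, jitter_sd = jitter_sd, seed = seed),
            class = "climate_sim_config")
}

#' Simulate a monthly climate table
#'
#' @param cfg a [climate_sim_config()].
#' @param site site label written to the table.
#' @return Data frame with `n_years * 12` rows: `site`, `year`, `month`,
#'   `precip_mm`, `et_mm`. The dry season occupies a contiguous mid-year
#'   block starting in June (southern-hemisphere style).
#' @export
gen_climate <- function(cfg, site = "sim") {
  stopifnot(inherits(cfg, "climate_sim_config"))
  d <- cfg$dry_months
  wet_val <- if (d < 12) (cfg$map_total - d * cfg$dry_month_precip) / (12 - d) else NA
  dry_idx <- if (d > 0) ((6:(5 + d) - 1) %% 12) + 1 else integer(0)
  base <- rep(wet_val, 12)
  base[dry_idx] <- cfg$dry_month_precip
  with_seed(cfg$seed, {
    rows <- lapply(seq_len(cfg$n_years), function(y) {
      p <- base
      if (cfg$jitter_sd > 0) {
        p <- pmax(p + stats::rnorm(12, 0, cfg$jitter_sd), 0)
        if (d > 0 && cfg$dry_month_precip < 100) p[dry_idx] <- pmin(p[dry_idx], 99.99)
        if (d < 12 && wet_val >= 100) p[-dry_idx] <- pmax(p[-dry_idx], 100)
      }
      data.frame(site = site, year = 2000 + y - 1, month = 1:12,
                 precip_mm = p, et_mm = cfg$et_monthly)
    })
    do.call(rbind, rows)
  })
}

#' Configuration for a simulated birth-death-growth census
#'
#' Mortality and recruitment act as independent exponential processes per
#' tree per interval, matching the instantaneous-rate formulation that the
#' dynamics module estimates. Initial diameters follow a reverse-J
#' (shifted exponential) stand structure above the 10 cm census threshold.
#'
#' @param n_trees0 initial number of live trees.
#' @param plot_area plot area (ha).
#' @param n_censuses number of censuses (>= 2).
#' @param interval_yr years between censuses.
#' @param annual_mortality per-capita mortality rate (yr^-1, in [0, 1)).
#' @param annual_recruitment per-capita recruitment rate (yr^-1, in [0, 1)).
#' @param dbh_growth_mean,dbh_growth_sd diameter growth (cm yr^-1); growth
#'   increments are truncated at zero so survivor DBH never decreases.
#' @param wd_mean,wd_sd species wood density distribution (g cm^-3).
#' @param n_species size of the species pool.
#' @param dbh0_scale mean of the initial DBH excess over 10 cm (cm).
#' @param start_year decimal year of the first census.
#' @param seed RNG seed.
#' @return A list of class `census_sim_config`.
#' @export
census_sim_config <- function(n_trees0 = 500, plot_area = 1, n_censuses = 2,
                              interval_yr = 5, annual_mortality = 0.015,
                              annual_recruitment = 0.015,
                              dbh_growth_mean = 0.2, dbh_growth_sd = 0.1,
                              wd_mean = 0.6, wd_sd = 0.08, n_species = 25,
                              dbh0_scale = 12, start_year = 2000, seed = 1) {
  check_number(annual_mortality, "annual_mortality", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_number(annual_recruitment, "annual_recruitment", lower = 0, upper = 1,
               strict_upper = TRUE)
  if (n_censuses < 2) abort("n_censuses must be >= 2")
  structure(list(n_trees0 = n_trees0, plot_area = plot_area,
                 n_censuses = n_censuses, interval_yr = interval_yr,
                 annual_mortality = annual_mortality,
                 annual_recruitment = annual_recruitment,
                 dbh_growth_mean = dbh_growth_mean,
                 dbh_growth_sd = dbh_growth_sd,
                 wd_mean = wd_mean, wd_sd = wd_sd, n_species = n_species,
                 dbh0_scale = dbh0_scale, start_year = start_year, seed = seed),
            class = "census_sim_config")
}

#' Simulate a long-format tree census table
#'
#' Each interval, every live tree survives with probability
#' `exp(-annual_mortality * interval)`; survivors add a non-negative
#' Gaussian diameter increment; dead trees get a single `dead` row carrying
#' their last measured DBH and never reappear; recruits enter at
#' `10 + |N(0, 0.5)|` cm with status `recruit`, their expected number being
#' `annual_recruitment * interval` per initially live tree.
#'
#' @param cfg a [census_sim_config()].
#' @param plot_id plot label written to the table.
#' @param init_trees optional data frame (`tree_id`, `species`,
#'   `wood_density`, `dbh`) fixing the initial stand instead of drawing it.
#' @return Long-format data frame: `plot_id`, `tree_id`, `species`,
#'   `wood_density`, `census_date`, `dbh`, `status`.
#' @export
gen_census <- function(cfg, plot_id = "sim", init_trees = NULL) {
  stopifnot(inherits(cfg, "census_sim_config"))
  with_seed(cfg$seed, {
    pool <- data.frame(
      species = sprintf("sp%02d", seq_len(cfg$n_species)),
      wd = pmin(pmax(stats::rnorm(cfg$n_species, cfg$wd_mean, cfg$wd_sd), 0.15), 1.2)
    )
    if (is.null(init_trees)) {
      sp_idx <- sample.int(cfg$n_species, cfg$n_trees0, replace = TRUE)
      trees <- data.frame(
        tree_id = sprintf("t%05d", seq_len(cfg$n_trees0)),
        species = pool$species[sp_idx],
        wood_density = pool$wd[sp_idx],
        dbh = 10 + stats::rexp(cfg$n_trees0, rate = 1 / cfg$dbh0_scale)
      )
    } else {
      check_columns(init_trees, c("tree_id", "species", "wood_density", "dbh"),
                    "init_trees")
      trees <- init_trees[, c("tree_id", "species", "wood_density", "dbh")]
    }
    n_next <- nrow(trees) + 1L
    alive <- rep(TRUE, nrow(trees))
    rows <- list(data.frame(plot_id = plot_id, tree_id = trees$tree_id,
                            species = trees$species,
                            wood_density = trees$wood_density,
                            census_date = cfg$start_year, dbh = trees$dbh,
                            status = "alive"))
    t <- cfg$interval_yr
    p_surv <- exp(-cfg$annual_mortality * t)
    for (k in seq_len(cfg$n_censuses - 1L)) {
      date <- cfg$start_year + k * t
      n_alive0 <- sum(alive)
      n_now <- nrow(trees)
      survive <- alive & (stats::runif(n_now) < p_surv)
      died <- alive & !survive
      grow <- pmax(stats::rnorm(n_now, cfg$dbh_growth_mean * t,
                                cfg$dbh_growth_sd * sqrt(t)), 0)
      trees$dbh[survive] <- trees$dbh[survive] + grow[survive]
      out_k <- list()
      if (any(survive)) {
        out_k$alive <- data.frame(plot_id = plot_id,
                                  tree_id = trees$tree_id[survive],
                                  species = trees$species[survive],
                                  wood_density = trees$wood_density[survive],
                                  census_date = date, dbh = trees$dbh[survive],
                                  status = "alive")
      }
      if (any(died)) {
        out_k$dead <- data.frame(plot_id = plot_id,
                                 tree_id = trees$tree_id[died],
                                 species = trees$species[died],
                                 wood_density = trees$wood_density[died],
                                 census_date = date, dbh = trees$dbh[died],
                                 status = "dead")
      }
      n_rec <- stats::rpois(1, cfg$annual_recruitment * n_alive0 * t)
      if (n_rec > 0) {
        sp_idx <- sample.int(cfg$n_species, n_rec, replace = TRUE)
        rec <- data.frame(
          tree_id = sprintf("t%05d", seq.int(n_next, length.out = n_rec)),
          species = pool$species[sp_idx],
          wood_density = pool$wd[sp_idx],
          dbh = 10 + abs(stats::rnorm(n_rec, 0, 0.5))
        )
        n_next <- n_next + n_rec
        out_k$rec <- data.frame(plot_id = plot_id, tree_id = rec$tree_id,
                                species = rec$species,
                                wood_density = rec$wood_density,
                                census_date = date, dbh = rec$dbh,
                                status = "recruit")
        trees <- rbind(trees, rec)
        survive <- c(survive, rep(TRUE, n_rec))
      }
      alive <- survive
      rows[[k + 1L]] <- do.call(rbind, out_k)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Configuration for a coupled multi-site scenario
#'
#' Defines the ground truth of a synthetic cross-site study: sites spread
#' over a water-deficit gradient, community hydraulic safety margins
#' optionally coupled to that gradient, and plot biomass dynamics coupled to
#' the community safety margin with a prescribed slope.
#'
#' @param n_sites number of sites (>= 4).
#' @param mcwd_range range (mm, both <= 0) from which site MCWD targets are
#'   drawn uniformly.
#' @param hsm_slope_true slope of site-mean HSM50 on MCWD (MPa mm^-1; 0
#'   decouples the safety margin from climate).
#' @param hsm_noise_sd site-level Gaussian noise on mean HSM50 (MPa).
#' @param dynamics_coupling slope of relative net biomass change on
#'   community-weighted-mean HSM50 (yr^-1 MPa^-1).
#' @param dagb_rel_base baseline relative net biomass change (yr^-1).
#' @param dyn_noise_sd site-level noise on the dynamics target (yr^-1).
#' @param hsm_mean grand mean HSM50 (MPa).
#' @param n_species species per site; `species_hsm_sd` their HSM spread.
#' @param species_hsm_sd within-site species HSM spread (MPa).
#' @param n_trees0,plot_area,interval_yr,n_censuses,annual_mortality,annual_recruitment,dbh_growth_sd
#'   census simulation settings (see [census_sim_config()]); diameter growth
#'   is calibrated per site to hit the dynamics target in expectation.
#' @param n_years_climate years of monthly climate per site.
#' @param seed RNG seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = 10, mcwd_range = c(-640, -15),
                            hsm_slope_true = 0.0025, hsm_noise_sd = 0.15,
                            dynamics_coupling = 0.01, dagb_rel_base = 0.003,
                            dyn_noise_sd = 0.001, hsm_mean = 0.4,
                            n_species = 12, species_hsm_sd = 0.25,
                            n_trees0 = 2200, plot_area = 4, interval_yr = 12,
                            n_censuses = 2, annual_mortality = 0.015,
                            annual_recruitment = 0.015, dbh_growth_sd = 0.15,
                            n_years_climate = 5, seed = 1) {
  if (n_sites < 4) abort("n_sites must be >= 4")
  if (any(mcwd_range > 0)) abort("mcwd_range values must be <= 0")
  structure(as.list(environment()), class = "scenario_config")
}

# expected relative net biomass change of a simulated plot as a function of
# the annual diameter growth g, used to calibrate g to a target
.expected_rel_dagb <- function(g, dbh0, wd, t, p_surv, exp_recruit_agb, cfg_allom) {
  a0 <- sum(tree_agb(dbh0, wd, cfg = cfg_allom))
  a_end <- p_surv * sum(tree_agb(dbh0 + g * t, wd, cfg = cfg_allom)) + exp_recruit_agb
  (a_end - a0) / t / ((a_end + a0) / 2)
}

#' Simulate a coupled multi-site scenario
#'
#' Generates, for every site: a monthly climate series whose MCWD equals the
#' site's drawn target; a species trait table (psi50, slope, psi88, psi_dry,
#' LMA, stem/branch wood density) whose basal-area-weighted HSM50 follows
#' the configured HSM-climate relationship; and a tree census whose
#' expected relative net biomass change equals
#' `dagb_rel_base + dynamics_coupling * CWM HSM50` (diameter growth is
#' calibrated per site against the realized initial stand, so in the
#' noise-free limit the coupling is exact). Ground-truth parameters are
#' returned alongside the data.
#'
#' @param cfg a [scenario_config()].
#' @return A list with elements `sites` (per-site truth: mcwd, mat, map,
#'   target dynamics, calibrated growth), `traits`, `abundance`, `climate`,
#'   `census` (long tables over all sites) and `config`.
#' @export
gen_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  allom <- allometry_config()
  with_seed(cfg$seed, {
    site_ids <- sprintf("site%02d", seq_len(cfg$n_sites))
    site_seeds <- sample.int(2^31 - 2, 3 * cfg$n_sites)
    mcwd_t <- stats::runif(cfg$n_sites, min(cfg$mcwd_range), max(cfg$mcwd_range))
    mat <- stats::rnorm(cfg$n_sites, 26, 0.8)
    hsm_site <- cfg$hsm_mean +
      cfg$hsm_slope_true * (mcwd_t - mean(cfg$mcwd_range)) +
      stats::rnorm(cfg$n_sites, 0, cfg$hsm_noise_sd)

    traits <- list(); abund <- list(); clim <- list(); cens <- list()
    cwm_hsm <- numeric(cfg$n_sites)
    target_rel <- numeric(cfg$n_sites)
    growth_cal <- numeric(cfg$n_sites)
    map_site <- numeric(cfg$n_sites)
    dyn_noise <- stats::rnorm(cfg$n_sites, 0, cfg$dyn_noise_sd)

    for (i in seq_len(cfg$n_sites)) {
      s <- site_ids[i]
      # climate with exact MCWD target: contiguous dry block
      d <- if (mcwd_t[i] < 0) min(12, ceiling(-mcwd_t[i] / 100)) else 0
      p_dry <- if (d > 0) 100 + mcwd_t[i] / d else 0
      map_site[i] <- max(3200 + 2.9 * mcwd_t[i],
                         d * p_dry + (12 - d) * 110)
      ccfg <- climate_sim_config(map_total = map_site[i], dry_months = d,
                                 dry_month_precip = p_dry, et_monthly = 100,
                                 n_years = cfg$n_years_climate,
                                 jitter_sd = 0, seed = site_seeds[i])
      clim[[i]] <- gen_climate(ccfg, site = s)

      # species traits: psi50 tracks the climate gradient, psi_dry places
      # each species at the site's safety margin plus spread
      psi50_site <- -1.55 + 0.00165 * mcwd_t[i]
      psi50_sp <- psi50_site + stats::rnorm(cfg$n_species, 0, 0.35)
      psi50_sp <- pmin(psi50_sp, -0.3)
      slope_sp <- pmax(stats::rnorm(cfg$n_species, 50, 10), 20)
      psi_dry_sp <- pmin(psi50_sp + hsm_site[i] +
                           stats::rnorm(cfg$n_species, 0, cfg$species_hsm_sd), -0.05)
      ba <- stats::rlnorm(cfg$n_species, log(0.8), 0.7)
      sp <- sprintf("%s_sp%02d", s, seq_len(cfg$n_species))
      traits[[i]] <- data.frame(
        site = s, species = sp, psi50 = psi50_sp, slope_s = slope_sp,
        psi88 = psi88_from_fit(psi50_sp, slope_sp), psi_dry = psi_dry_sp,
        hsm50 = psi_dry_sp - psi50_sp,
        lma = stats::rnorm(cfg$n_species, 110, 20),
        wd_stem = pmin(pmax(stats::rnorm(cfg$n_species, 0.62, 0.06), 0.2), 1.1),
        wd_branch = pmin(pmax(stats::rnorm(cfg$n_species, 0.55, 0.06), 0.2), 1.1)
      )
      abund[[i]] <- data.frame(site = s, species = sp, basal_area = ba)
      cwm_hsm[i] <- sum(ba * traits[[i]]$hsm50) / sum(ba)
      target_rel[i] <- cfg$dagb_rel_base +
        cfg$dynamics_coupling * (cwm_hsm[i] - cfg$hsm_mean) + dyn_noise[i]

      # census: draw the initial stand, then calibrate diameter growth so
      # the expected relative biomass change hits the site target
      n0 <- cfg$n_trees0
      init <- data.frame(
        tree_id = sprintf("%s_t%05d", s, seq_len(n0)),
        species = sample(sp, n0, replace = TRUE),
        wood_density = pmin(pmax(stats::rnorm(n0, 0.6, 0.08), 0.2), 1.1),
        dbh = 10 + stats::rexp(n0, 1 / 12)
      )
      t_int <- cfg$interval_yr
      p_surv <- exp(-cfg$annual_mortality * t_int)
      exp_rec_agb <- cfg$annual_recruitment * n0 * t_int *
        tree_agb(10 + 0.5 * sqrt(2 / pi), 0.6, cfg = allom)
      f <- function(g) .expected_rel_dagb(g, init$dbh, init$wood_density,
                                          t_int, p_surv, exp_rec_agb, allom) -
        target_rel[i]
      g_cal <- if (f(0) >= 0) 0 else stats::uniroot(f, c(0, 3), tol = 1e-12)$root
      growth_cal[i] <- g_cal
      censcfg <- census_sim_config(
        n_trees0 = n0, plot_area = cfg$plot_area, n_censuses = cfg$n_censuses,
        interval_yr = t_int, annual_mortality = cfg$annual_mortality,
        annual_recruitment = cfg$annual_recruitment,
        dbh_growth_mean = g_cal, dbh_growth_sd = cfg$dbh_growth_sd,
        n_species = cfg$n_species, seed = site_seeds[cfg$n_sites + i])
      cens[[i]] <- gen_census(censcfg, plot_id = s, init_trees = init)
    }

    list(
      sites = data.frame(site = site_ids, mcwd_true = mcwd_t, mat = mat,
                         map_true = map_site, hsm_site = hsm_site,
                         cwm_hsm_true = cwm_hsm, target_rel_dagb = target_rel,
                         growth_calibrated = growth_cal),
      traits = do.call(rbind, traits),
      abundance = do.call(rbind, abund),
      climate = do.call(rbind, clim),
      census = do.call(rbind, cens),
      config = cfg
    )
  })
}

#' Per-site analysis table from a scenario bundle
#'
#' Runs the real pipeline modules over a [gen_scenario()] bundle: climate
#' summaries ([climate_summary()]), plot dynamics ([plot_dynamics()]) and
#' basal-area weighted community means ([cwm()]), and joins them into the
#' one-row-per-site table that [predictor_screen()] consumes.
#'
#' @param scn a list returned by [gen_scenario()].
#' @param cfg_allom an [allometry_config()].
#' @return Data frame with one row per site: `dagb_rel`, `agwp_rel`,
#'   `agb_mort_rel`, `stem_mort_rate`, `tau_w`, climate (`mat`, `map`,
#'   `mcwd`) and CWM traits (`psi50`, `psi_dry`, `hsm50`, `wd_stem`,
#'   `wd_branch`, `lma`).
#' @export
scenario_site_table <- function(scn, cfg_allom = allometry_config()) {
  cs <- climate_summary(scn$climate,
                        mat = data.frame(site = scn$sites$site, mat = scn$sites$mat),
                        e_mode = "top3", mcwd_mode = "per_year_mean")
  dyn <- lapply(split(scn$census, scn$census$plot_id), plot_dynamics,
                plot_area = scn$config$plot_area, cfg = cfg_allom)
  dyn_df <- do.call(rbind, lapply(dyn, function(d) {
    data.frame(site = as.character(d$plot_id), dagb_rel = d$dagb_rel,
               agwp_rel = d$agwp_rel, agb_mort_rel = d$agb_mort_rel,
               stem_mort_rate = d$stem_mort_rate_std, tau_w = d$tau_w)
  }))
  tr <- merge(scn$traits, scn$abundance, by = c("site", "species"))
  cwm_df <- do.call(rbind, lapply(split(tr, tr$site), function(df) {
    vals <- vapply(c("psi50", "psi_dry", "hsm50", "wd_stem", "wd_branch", "lma"),
                   function(v) cwm(df[[v]], df$basal_area)$cwm, 0)
    cbind(data.frame(site = df$site[1]), as.data.frame(as.list(vals)))
  }))
  out <- merge(merge(dyn_df, cs[, c("site", "mcwd", "map", "mat")], by = "site"),
               cwm_df, by = "site")
  rownames(out) <- NULL
  out
}
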