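# Plot-level carbon dynamics from repeated tree-by-tree censuses.

#' Rules for estimating unobserved census components
#'
#' Census intervals miss two fluxes: recruits that both entered and died
#' within the interval, and the growth that dying trees put on before death.
#' Both are estimated and credited to production and to mortality alike, so
#' they cancel in the net balance. Unobserved recruit deaths are
#' approximated as `recruit_rate * mortality_rate * t^2 / 2` trees (uniform
#' arrival, exponential death), each entering biomass at the census
#' threshold diameter; each observed death is credited the median survivor
#' biomass growth rate for `growth_credit_fraction` of the interval.
#'
#' @param growth_credit_fraction fraction of the interval for which a dying
#'   tree is credited growth (default 0.5).
#' @param recruit_dbh diameter (cm) at which unobserved recruits are valued
#'   (default 10, the census threshold).
#' @param unobserved_recruits logical; estimate component (3) at all.
#' @return A list of class `dynamics_rules`.
#' @export
dynamics_rules <- function(growth_credit_fraction = 0.5, recruit_dbh = 10,
                           unobserved_recruits = TRUE) {
  structure(list(growth_credit_fraction = growth_credit_fraction,
                 recruit_dbh = recruit_dbh,
                 unobserved_recruits = unobserved_recruits),
            class = "dynamics_rules")
}

.live_status <- c("alive", "recruit")

# rows of one census date with per-tree AGB attached
.census_slice <- function(census, date, cfg) {
  rows <- census[census$census_date == date & census$status %in% .live_status, ,
                 drop = FALSE]
  rows$agb_kg <- tree_agb(rows$dbh, rows$wood_density, cfg = cfg)
  rows
}

#' Stand biomass at one census
#'
#' Sums live-tree aboveground biomass and scales to Mg per hectare.
#'
#' @param census census rows at a single date (columns `tree_id`,
#'   `wood_density`, `dbh`, `status`); rows whose status is not
#'   `alive`/`recruit` are ignored.
#' @param plot_area plot area in ha (> 0).
#' @param cfg an [allometry_config()].
#' @return Stand biomass in Mg ha^-1.
#' @export
plot_agb <- function(census, plot_area, cfg = allometry_config()) {
  check_number(plot_area, "plot_area", lower = 0, strict_lower = TRUE)
  live <- census[census$status %in% .live_status, , drop = FALSE]
  if (!nrow(live)) return(0)
  sum(tree_agb(live$dbh, live$wood_density, cfg = cfg)) / 1000 / plot_area
}

#' Net annual aboveground biomass change
#'
#' `(agb_end - agb_start) / years`; negative values (net biomass loss) are
#' preserved.
#'
#' @param agb_start,agb_end stand biomass (Mg ha^-1) at the first and last
#'   census used.
#' @param years monitoring length in years (> 0).
#' @return Mg ha^-1 yr^-1.
#' @export
delta_agb <- function(agb_start, agb_end, years) {
  if (any(years <= 0)) abort("monitoring length must be > 0 years")
  (agb_end - agb_start) / years
}

#' Annual instantaneous stem mortality rate
#'
#' `100 * (ln(A) - ln(B)) / interval`, with `A` the stems alive at the start
#' of the interval and `B` those that survived it. Being ratio-based, the
#' rate is identical whether counts are per plot or per hectare.
#'
#' @param a_stems initial live stem count (> 0).
#' @param b_survivors surviving stem count (0 < B <= A).
#' @param interval census interval in years (> 0).
#' @return Rate in % yr^-1.
#' @export
stem_mortality_rate <- function(a_stems, b_survivors, interval) {
  if (any(interval <= 0)) abort("census interval must be > 0")
  if (any(b_survivors <= 0)) abort("survivor count must be > 0 (log undefined)")
  if (any(b_survivors > a_stems)) abort("survivors cannot exceed initial stems")
  (log(a_stems) - log(b_survivors)) / interval * 100
}

#' Standardize a rate to a common census interval
#'
#' Demographic rates estimated over long intervals are biased low because
#' deaths go unseen; `rate * (interval / ref_interval)^exponent` corrects
#' towards a reference interval. The default exponent 0.08 follows the
#' standard census-interval correction; it is configurable because published
#' analyses rarely print it.
#'
#' @param rate rate in % yr^-1.
#' @param interval census interval (yr).
#' @param ref_interval reference interval (yr, default 1).
#' @param exponent correction exponent (default 0.08; 0 disables).
#' @return Corrected rate in % yr^-1.
#' @export
standardize_rate <- function(rate, interval, ref_interval = 1, exponent = 0.08) {
  if (any(c(interval, ref_interval) <= 0)) abort("intervals must be > 0")
  rate * (interval / ref_interval)^exponent
}

#' Woody biomass residence time
#'
#' Ratio of the time-weighted mean standing biomass to the time-weighted
#' mean annual biomass mortality.
#'
#' @param agb_tw_mean standing biomass (Mg ha^-1).
#' @param agb_mort_tw_mean biomass mortality flux (Mg ha^-1 yr^-1).
#' @return Residence time in years; `NA` with a warning when mortality is
#'   zero.
#' @export
residence_time <- function(agb_tw_mean, agb_mort_tw_mean) {
  if (agb_mort_tw_mean <= 0) {
    warnf("zero biomass mortality: residence time undefined")
    return(NA_real_)
  }
  agb_tw_mean / agb_mort_tw_mean
}

# fluxes for one census interval of one plot; internal engine behind
# agwp() and agb_mortality()
.interval_fluxes <- function(census, date_a, date_b, plot_area, cfg, rules) {
  t <- date_b - date_a
  if (t <= 0) abort("census dates must be strictly increasing")
  a <- .census_slice(census, date_a, cfg)
  b <- .census_slice(census, date_b, cfg)

  new_ids <- setdiff(b$tree_id, a$tree_id)
  bad <- b$tree_id %in% new_ids & b$status != "recruit"
  if (any(bad)) {
    abort("unmatched tree ids at census %.2f (present but not recruits): %s",
          date_b, paste(unique(b$tree_id[bad]), collapse = ", "))
  }

  surv_ids <- intersect(a$tree_id, b$tree_id)
  dead_ids <- setdiff(a$tree_id, b$tree_id)
  rec_ids <- new_ids

  agb_a <- a$agb_kg[match(surv_ids, a$tree_id)]
  agb_b <- b$agb_kg[match(surv_ids, b$tree_id)]
  survivor_growth <- sum(agb_b - agb_a)
  recruit_agb <- sum(b$agb_kg[match(rec_ids, b$tree_id)])
  dead_agb <- sum(a$agb_kg[match(dead_ids, a$tree_id)])

  n_a <- nrow(a)
  n_surv <- length(surv_ids)

  # (4) unobserved growth of trees that died: median survivor growth rate
  # credited for a fraction of the interval
  med_growth <- if (n_surv > 0) stats::median((agb_b - agb_a) / t) else 0
  unobs_dying_growth <- length(dead_ids) * med_growth * t * rules$growth_credit_fraction

  # (3) unobserved recruits that died before being recorded
  unobs_recruit <- 0
  if (rules$unobserved_recruits && length(rec_ids) > 0 &&
      n_surv > 0 && length(dead_ids) > 0) {
    rec_rate <- length(rec_ids) / t                        # trees yr^-1
    mort_rate <- (log(n_a) - log(n_surv)) / t              # yr^-1 per capita
    n_unobs <- rec_rate * mort_rate * t^2 / 2
    wd_ref <- mean(b$wood_density[match(rec_ids, b$tree_id)])
    unobs_recruit <- n_unobs * tree_agb(rules$recruit_dbh, wd_ref, cfg = cfg)
  }

  scale <- 1 / t / 1000 / plot_area  # kg per interval -> Mg ha^-1 yr^-1
  data.frame(
    date_start = date_a, date_end = date_b, interval_yr = t,
    agb_start = sum(a$agb_kg) / 1000 / plot_area,
    agb_end = sum(b$agb_kg) / 1000 / plot_area,
    n_stems_start = n_a, n_survivors = n_surv,
    n_recruits = length(rec_ids), n_deaths = length(dead_ids),
    survivor_growth = survivor_growth * scale,
    recruit_agb = recruit_agb * scale,
    unobs_recruit_growth = unobs_recruit * scale,
    unobs_dying_growth = unobs_dying_growth * scale,
    agwp = (survivor_growth + recruit_agb + unobs_recruit + unobs_dying_growth) * scale,
    agb_mort = (dead_agb + unobs_recruit + unobs_dying_growth) * scale,
    stem_mort_rate = if (n_surv > 0) stem_mortality_rate(n_a, n_surv, t) else NA_real_
  )
}

#' Annual aboveground wood production over a census interval
#'
#' Sum of four components divided by the interval length: (1) growth of
#' surviving trees, (2) biomass of new recruits, (3) estimated growth of
#' unobserved recruits that died within the interval and (4) estimated
#' unobserved growth of trees that died (see [dynamics_rules()]).
#'
#' @param census long-format census rows of a single plot (columns
#'   `tree_id`, `wood_density`, `census_date`, `dbh`, `status`).
#' @param date_a,date_b two consecutive census dates present in the table;
#'   defaults to the first two.
#' @param plot_area plot area (ha).
#' @param cfg an [allometry_config()].
#' @param rules a [dynamics_rules()].
#' @return One-row data frame with the component breakdown and `agwp`
#'   (Mg ha^-1 yr^-1).
#' @export
agwp <- function(census, plot_area, date_a = NULL, date_b = NULL,
                 cfg = allometry_config(), rules = dynamics_rules()) {
  dates <- sort(unique(census$census_date))
  if (length(dates) < 2) abort("need two censuses")
  .interval_fluxes(census, date_a %||% dates[1], date_b %||% dates[2],
                   plot_area, cfg, rules)
}

#' Annual aboveground biomass mortality over a census interval
#'
#' Biomass of trees that died (valued at their last live census) plus the
#' same unobserved-growth estimates credited to production, divided by the
#' interval. Sharing those estimates guarantees that
#' `delta AGB = AGWP - AGB_MORT` holds exactly.
#'
#' @inheritParams agwp
#' @return Mortality flux in Mg ha^-1 yr^-1.
#' @export
agb_mortality <- function(census, plot_area, date_a = NULL, date_b = NULL,
                          cfg = allometry_config(), rules = dynamics_rules()) {
  agwp(census, plot_area, date_a, date_b, cfg, rules)$agb_mort
}

#' Full plot-level dynamics from a multi-census table
#'
#' Runs every census interval of one plot through the flux engine and
#' aggregates to one row per plot: biomass stocks, time-weighted mean
#' standing biomass (trapezoidal over intervals), net change, production and
#' mortality fluxes (time-weighted means across intervals), stem mortality
#' rate (raw and interval-standardized), woody residence time, and relative
#' forms of each flux. Rows flagged as monocots (optional logical `monocot`
#' column) are excluded from all biomass and stem counts.
#'
#' @param census long-format census rows of one plot.
#' @param plot_area plot area (ha).
#' @param cfg an [allometry_config()].
#' @param rules a [dynamics_rules()].
#' @param std_exponent,ref_interval census-interval standardization for the
#'   stem mortality rate (see [standardize_rate()]).
#' @return A list of class `plot_dynamics` with fields described above and
#'   the per-interval table in `$intervals`.
#' @export
plot_dynamics <- function(census, plot_area, cfg = allometry_config(),
                          rules = dynamics_rules(), std_exponent = 0.08,
                          ref_interval = 1) {
  check_columns(census, c("tree_id", "wood_density", "census_date", "dbh", "status"),
                "census table")
  if ("monocot" %in% names(census)) {
    census <- census[!isTRUE_vec(census$monocot), , drop = FALSE]
  }
  dates <- sort(unique(census$census_date))
  if (length(dates) < 2) abort("need at least two censuses, got %d", length(dates))

  ints <- do.call(rbind, lapply(seq_len(length(dates) - 1), function(i) {
    .interval_fluxes(census, dates[i], dates[i + 1], plot_area, cfg, rules)
  }))

  total_yr <- sum(ints$interval_yr)
  tw <- function(x) sum(x * ints$interval_yr) / total_yr
  agb_start <- ints$agb_start[1]
  agb_end <- ints$agb_end[nrow(ints)]
  agb_tw_mean <- tw((ints$agb_start + ints$agb_end) / 2)

  raw_rate <- tw(ints$stem_mort_rate)
  std_rate <- tw(standardize_rate(ints$stem_mort_rate, ints$interval_yr,
                                  ref_interval, std_exponent))
  agb_mort_tw <- tw(ints$agb_mort)

  out <- list(
    plot_id = if ("plot_id" %in% names(census)) census$plot_id[1] else NA,
    plot_area = plot_area,
    monitoring_years = total_yr,
    n_censuses = length(dates),
    agb_start = agb_start, agb_end = agb_end, agb_tw_mean = agb_tw_mean,
    dagb_abs = delta_agb(agb_start, agb_end, total_yr),
    agwp = tw(ints$agwp),
    agwp_components = c(survivor_growth = tw(ints$survivor_growth),
                        recruit_agb = tw(ints$recruit_agb),
                        unobs_recruit_growth = tw(ints$unobs_recruit_growth),
                        unobs_dying_growth = tw(ints$unobs_dying_growth)),
    agb_mort = agb_mort_tw,
    stem_mort_rate = raw_rate,
    stem_mort_rate_std = std_rate,
    tau_w = if (agb_mort_tw > 0) agb_tw_mean / agb_mort_tw else NA_real_,
    intervals = ints
  )
  class(out) <- "plot_dynamics"
  relative_metrics(out)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Relative (per standing biomass) forms of the plot fluxes
#'
#' Divides each absolute flux by the time-weighted mean standing biomass,
#' giving rates in yr^-1; `agb_mort_rel` is the reciprocal of the residence
#' time.
#'
#' @param dyn a `plot_dynamics` object.
#' @return The object with `dagb_rel`, `agwp_rel`, `agb_mort_rel` added.
#' @export
relative_metrics <- function(dyn) {
  if (!inherits(dyn, "plot_dynamics")) abort("dyn must be a plot_dynamics object")
  if (dyn$agb_tw_mean <= 0) abort("time-weighted standing biomass must be > 0")
  dyn$dagb_rel <- dyn$dagb_abs / dyn$agb_tw_mean
  dyn$agwp_rel <- dyn$agwp / dyn$agb_tw_mean
  dyn$agb_mort_rel <- dyn$agb_mort / dyn$agb_tw_mean
  dyn
}

#' @export
print.plot_dynamics <- function(x, ...) {
  cat(sprintf("Plot %s: %.1f yr over %d censuses, %.2f ha\n",
              as.character(x$plot_id), x$monitoring_years, x$n_censuses,
              x$plot_area))
  cat(sprintf("  AGB %.1f -> %.1f Mg/ha (tw mean %.1f)\n",
              x$agb_start, x$agb_end, x$agb_tw_mean))
  cat(sprintf("  dAGB %.3f, AGWP %.3f, AGB_MORT %.3f Mg/ha/yr\n",
              x$dagb_abs, x$agwp, x$agb_mort))
  cat(sprintf("  stem mortality %.2f %%/yr (std %.2f), tau_w %.1f yr\n",
              x$stem_mort_rate, x$stem_mort_rate_std, x$tau_w))
  invisible(x)
}

#' Merge small neighbouring plots
#'
#' Plots smaller than `max_area_ha` that lie within `max_distance_m` of each
#' other (great-circle distance on lat/lon) are combined and treated as a
#' single plot. Merging is by connected components, so a chain of close
#' small plots collapses into one unit; plots at or above the size threshold
#' are never merged.
#'
#' @param plots data frame with columns `plot_id`, `area_ha` and, for plots
#'   below the size threshold, `lat` and `lon` (decimal degrees).
#' @param max_area_ha size threshold (default 0.5 ha).
#' @param max_distance_m distance threshold (default 1000 m).
#' @return The input with columns `merged_id` (new unit label) and
#'   `merged_area_ha` added.
#' @export
merge_small_plots <- function(plots, max_area_ha = 0.5, max_distance_m = 1000) {
  check_columns(plots, c("plot_id", "area_ha"), "plot table")
  n <- nrow(plots)
  small <- plots$area_ha < max_area_ha
  if (any(small)) {
    check_columns(plots, c("lat", "lon"), "plot table")
    if (any(is.na(plots$lat[small]) | is.na(plots$lon[small]))) {
      abort("missing coordinates for plots below %.2f ha: %s", max_area_ha,
            paste(plots$plot_id[small & (is.na(plots$lat) | is.na(plots$lon))],
                  collapse = ", "))
    }
  }
  comp <- seq_len(n)
  idx <- which(small)
  if (length(idx) > 1) {
    for (i in idx) {
      for (j in idx[idx > i]) {
        d <- geosphere::distHaversine(c(plots$lon[i], plots$lat[i]),
                                      c(plots$lon[j], plots$lat[j]))
        if (d <= max_distance_m) {
          comp[comp == comp[j]] <- comp[i]
        }
      }
    }
  }
  plots$merged_id <- vapply(comp, function(k) {
    members <- sort(as.character(plots$plot_id[comp == k]))
    paste(members, collapse = "+")
  }, "")
  plots$merged_area_ha <- as.numeric(tapply(plots$area_ha, comp, sum)[as.character(comp)])
  plots
}

#' Select the census window for dynamics analyses
#'
#' Applies the analysis-window policy: censuses from `end_cutoff` (default
#' 2015) onwards are dropped; censuses before `start_cutoff` (default 2000)
#' are dropped unless the remaining window is shorter than `min_years`, in
#' which case the single census immediately preceding the start cutoff is
#' re-admitted. Plots that cannot retain two censuses are excluded with a
#' reason.
#'
#' @param dates numeric census dates (decimal years) of one plot.
#' @param min_years minimum monitoring length aimed for (default 10).
#' @param start_cutoff,end_cutoff window boundaries (decimal years).
#' @return A list: `dates` (retained, sorted), `monitoring_years`,
#'   `flagged` (TRUE when the retained window is still shorter than
#'   `min_years`), `excluded`, `reason`.
#' @export
select_censuses <- function(dates, min_years = 10, start_cutoff = 2000,
                            end_cutoff = 2015) {
  dates <- sort(unique(dates))
  kept <- dates[dates < end_cutoff]
  pre <- kept[kept < start_cutoff]
  win <- kept[kept >= start_cutoff]
  span <- function(x) if (length(x) >= 2) max(x) - min(x) else 0
  if (span(win) < min_years && length(pre)) {
    win <- c(max(pre), win)  # admit the census immediately before the cutoff
  }
  if (length(win) < 2) {
    return(list(dates = numeric(0), monitoring_years = 0, flagged = FALSE,
                excluded = TRUE,
                reason = "fewer than two censuses after window selection"))
  }
  list(dates = win, monitoring_years = span(win),
       flagged = span(win) < min_years, excluded = FALSE, reason = NA_character_)
}
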