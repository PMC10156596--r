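# Climatological water-deficit metrics from monthly precipitation and
# evapotranspiration tables.

#' Evapotranspiration demand for the water-deficit calculation
#'
#' A single monthly evapotranspiration demand per site. In `"top3"` mode the
#' monthly ET climatology (mean per calendar month across years) is built and
#' the mean of its three largest values returned, representing peak
#' atmospheric demand; `"fixed100"` returns the conventional flat demand of
#' 100 mm per month regardless of the data.
#'
#' @param clim data frame with columns `year`, `month`, and `et_mm`
#'   (ignored in fixed mode); a single site.
#' @param mode `"top3"` or `"fixed100"`.
#' @return Demand in mm month^-1.
#' @export
select_e_demand <- function(clim, mode = c("top3", "fixed100")) {
  mode <- match.arg(mode)
  if (mode == "fixed100") return(100)
  check_columns(clim, c("month", "et_mm"), "climate table")
  if (nrow(clim) < 12 || all(is.na(clim$et_mm))) {
    abort("top3 mode needs at least 12 months of et_mm data")
  }
  climatology <- tapply(clim$et_mm, clim$month, mean, na.rm = TRUE)
  mean(sort(climatology, decreasing = TRUE)[1:3])
}

#' Cumulative water deficit over one calendar year
#'
#' Sequential water balance `CWD[n] = CWD[n-1] + P[n] - E`, capped at zero
#' after each month (a saturated column carries no surplus), starting from
#' zero in January. All outputs are <= 0.
#'
#' @param precip 12 monthly precipitation values (mm), January first.
#' @param e_demand evapotranspiration demand, a single value (mm month^-1)
#'   or 12 monthly values.
#' @return Numeric vector of 12 monthly CWD values (mm, <= 0).
#' @export
cwd_series <- function(precip, e_demand) {
  if (length(precip) != 12) abort("precip must have 12 monthly values, got %d", length(precip))
  if (any(precip < 0, na.rm = TRUE)) abort("precipitation must be >= 0")
  e <- rep_len(e_demand, 12)
  cwd <- numeric(12)
  prev <- 0
  for (n in 1:12) {
    prev <- min(prev + precip[n] - e[n], 0)
    cwd[n] <- prev
  }
  cwd
}

#' Maximum cumulative water deficit
#'
#' The most negative monthly cumulative water deficit within a calendar
#' year, `MCWD = min(CWD[1], ..., CWD[12])`. With `mode = "per_year_mean"`
#' (the long-term mean) the MCWD is computed for each complete calendar year
#' and averaged; `"climatology"` first averages precipitation by calendar
#' month and makes a single pass. Incomplete years are dropped with a
#' warning.
#'
#' @param clim data frame with columns `year`, `month`, `precip_mm` for a
#'   single site.
#' @param e_demand demand in mm month^-1 (see [select_e_demand()]).
#' @param mode `"per_year_mean"` or `"climatology"`.
#' @return MCWD in mm (<= 0).
#' @export
mcwd <- function(clim, e_demand, mode = c("per_year_mean", "climatology")) {
  mode <- match.arg(mode)
  clim <- .complete_years(clim)
  if (mode == "climatology") {
    p_bar <- tapply(clim$precip_mm, clim$month, mean)
    return(min(cwd_series(as.numeric(p_bar[order(as.numeric(names(p_bar)))]), e_demand)))
  }
  per_year <- vapply(split(clim, clim$year), function(df) {
    min(cwd_series(df$precip_mm[order(df$month)], e_demand))
  }, 0)
  mean(per_year)
}

# keep only years with all 12 months present
.complete_years <- function(clim) {
  check_columns(clim, c("year", "month", "precip_mm"), "climate table")
  n_months <- tapply(clim$month, clim$year, function(m) length(unique(m)))
  complete <- names(n_months)[n_months == 12]
  if (!length(complete)) abort("no complete calendar years in climate table")
  if (length(complete) < length(n_months)) {
    warnf("dropping %d incomplete year(s) from climate table",
          length(n_months) - length(complete))
  }
  clim[clim$year %in% as.numeric(complete), ]
}

#' Dry-season length
#'
#' Number of calendar months whose climatological (multi-year mean)
#' precipitation is below 100 mm.
#'
#' @inheritParams mcwd
#' @param threshold_mm dry-month threshold (default 100 mm).
#' @return Integer count of months, 0-12.
#' @export
dry_season_length <- function(clim, threshold_mm = 100) {
  clim <- .complete_years(clim)
  p_bar <- tapply(clim$precip_mm, clim$month, mean)
  sum(p_bar < threshold_mm)
}

#' Classify a site into a seasonality forest type
#'
#' Three classes by dry-season length: `ecotonal_long_dsl` (DSL >= 6
#' months), `intermediate_dsl` (2-5 months) and `aseasonal` (DSL <= 1; the
#' published classes leave DSL = 1 undefined and it is assigned to the
#' nearest, aseasonal, class).
#'
#' @param dsl dry-season length in months (vectorized).
#' @return Character vector of forest types.
#' @export
classify_forest_type <- function(dsl) {
  ifelse(dsl >= 6, "ecotonal_long_dsl",
         ifelse(dsl >= 2, "intermediate_dsl", "aseasonal"))
}

#' Per-site climate summary
#'
#' Computes MCWD, mean annual precipitation, dry-season length,
#' evapotranspiration demand and forest type for every site in a monthly
#' climate table. Mean annual temperature is a pass-through value supplied
#' by the caller (it comes from gridded products outside this package's
#' scope).
#'
#' @param clim data frame with columns `site`, `year`, `month`, `precip_mm`
#'   and, unless `e_mode = "fixed100"`, `et_mm`.
#' @param mat optional data frame (`site`, `mat`) of mean annual
#'   temperatures to carry through.
#' @param e_mode passed to [select_e_demand()].
#' @param mcwd_mode passed to [mcwd()].
#' @return Data frame with one row per site: `site`, `mcwd`, `map`, `mat`,
#'   `dsl`, `e_demand`, `forest_type`, `mcwd_mode`, `e_mode`.
#' @export
climate_summary <- function(clim, mat = NULL,
                            e_mode = c("top3", "fixed100"),
                            mcwd_mode = c("per_year_mean", "climatology")) {
  e_mode <- match.arg(e_mode)
  mcwd_mode <- match.arg(mcwd_mode)
  check_columns(clim, c("site", "year", "month", "precip_mm"), "climate table")
  rows <- lapply(split(clim, clim$site), function(df) {
    e <- select_e_demand(df, mode = e_mode)
    dfc <- suppressWarnings(.complete_years(df))
    data.frame(
      site = df$site[1],
      mcwd = mcwd(df, e, mode = mcwd_mode),
      map = mean(tapply(dfc$precip_mm, dfc$year, sum)),
      dsl = dry_season_length(df),
      e_demand = e,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$forest_type <- classify_forest_type(out$dsl)
  out$mcwd_mode <- mcwd_mode
  out$e_mode <- e_mode
  if (!is.null(mat)) {
    check_columns(mat, c("site", "mat"), "mat table")
    out <- merge(out, mat, by = "site", all.x = TRUE)
  } else {
    out$mat <- NA_real_
  }
  out
}
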