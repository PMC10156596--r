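# CSV readers with schema validation and the pipeline driver.

# required and numeric columns per interchange schema
.schemas <- list(
  curves = list(required = c("branch_id", "species", "site", "psi_mpa"),
                numeric = c("psi_mpa", "air_discharge", "pad")),
  potentials = list(required = c("species", "site", "individual_id", "leaf_psi_mpa"),
                    numeric = "leaf_psi_mpa"),
  climate = list(required = c("site", "year", "month", "precip_mm"),
                 numeric = c("year", "month", "precip_mm", "et_mm")),
  census = list(required = c("plot_id", "tree_id", "wood_density",
                             "census_date", "dbh", "status"),
                numeric = c("wood_density", "census_date", "dbh")),
  traits = list(required = c("site", "species"),
                numeric = c("psi50", "psi88", "psi_dry", "lma",
                            "wd_stem", "wd_branch")),
  abundance = list(required = c("site", "species", "basal_area"),
                   numeric = "basal_area"),
  plots = list(required = c("plot_id", "area_ha"),
               numeric = c("area_ha", "lat", "lon"))
)

#' Read and validate an interchange CSV table
#'
#' Reads an RFC 4180 CSV (UTF-8, "." decimal), checks the required columns
#' of the named schema, and coerces the schema's numeric columns, reporting
#' the first offending row when a value does not parse. Unknown columns are
#' preserved.
#'
#' @param path file path.
#' @param schema one of `"curves"`, `"potentials"`, `"climate"`, `"census"`,
#'   `"traits"`, `"abundance"`, `"plots"`.
#' @return A validated data frame.
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(.schemas))
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  spec <- .schemas[[schema]]
  check_columns(df, spec$required, sprintf("%s table '%s'", schema, basename(path)))
  for (col in intersect(spec$numeric, names(df))) {
    if (is.numeric(df[[col]])) next
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]) & df[[col]] != "" &
                   df[[col]] != "NA")
    if (length(bad)) {
      abort("column '%s' of %s: unparseable numeric value '%s' at row %d",
            col, basename(path), df[[col]][bad[1]], bad[1])
    }
    df[[col]] <- parsed
  }
  df
}

.write_out <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Chains all stages over CSV inputs: vulnerability-curve fitting per
#' species and site, dry-season water potentials and safety margins,
#' per-site climate summaries, plot dynamics, community-weighted trait
#' means, and the predictor screen of relative net biomass change. Each
#' stage writes a CSV under `config$out_dir`; a run manifest (configuration
#' snapshot, per-stage row counts, collected warnings) is written as JSON.
#'
#' @param config a list with file paths (`curves`, `potentials`, `climate`,
#'   `census`, `traits`, `abundance`, `plot_areas` named numeric vector or
#'   NULL), `out_dir`, and options: `strategy`, `e_mode`, `mcwd_mode`,
#'   `bootstrap_n`, `seed`, `bonferroni_m`, `excluded_plots`, `mat` (data
#'   frame site/mat), `std_exponent`.
#' @return Invisibly, a list with every stage's output and the manifest.
#' @export
run_all <- function(config) {
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  log_warn <- function(stage) function(w) {
    warnings_log <<- c(warnings_log, sprintf("[%s] %s", stage, conditionMessage(w)))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort("stage '%s' failed: %s", name, conditionMessage(e))
      }),
      warning = log_warn(name))
  }

  # 1. vulnerability curves -> species x site psi50/psi88
  curves <- stage("fit-curves", {
    cv <- read_table(config$curves, "curves")
    if (!"pad" %in% names(cv)) cv <- normalize_air_discharge(cv)
    key <- interaction(cv$species, cv$site, drop = TRUE)
    fits <- lapply(split(cv, key), species_site_fit,
                   strategy = config$strategy %||% "pooled",
                   bootstrap_n = config$bootstrap_n %||% 0,
                   seed = config$seed %||% NULL)
    do.call(rbind, lapply(names(fits), function(k) {
      f <- fits[[k]]
      df <- cv[key == k, ][1, c("species", "site")]
      data.frame(df, psi50 = f$psi50, slope_s = f$slope_s, psi88 = f$psi88,
                 ci_psi50_lo = f$ci_psi50[1], ci_psi50_hi = f$ci_psi50[2],
                 n_points = f$n_points, converged = f$converged)
    }))
  })
  .write_out(curves, file.path(out_dir, "curve_fits.csv"))

  # 2. safety margins
  hydraulics <- stage("hsm", {
    pots <- read_table(config$potentials, "potentials")
    species_hydraulics(pots, curves)
  })
  .write_out(hydraulics, file.path(out_dir, "species_hydraulics.csv"))

  # 3. climate
  clim_sum <- stage("climate", {
    clim <- read_table(config$climate, "climate")
    climate_summary(clim, mat = config$mat %||% NULL,
                    e_mode = config$e_mode %||% "top3",
                    mcwd_mode = config$mcwd_mode %||% "per_year_mean")
  })
  .write_out(clim_sum, file.path(out_dir, "climate_summary.csv"))

  # 4. forest dynamics
  dynamics <- stage("dynamics", {
    cen <- read_table(config$census, "census")
    cen <- cen[!cen$plot_id %in% (config$excluded_plots %||% character(0)), ]
    areas <- config$plot_areas
    do.call(rbind, lapply(split(cen, cen$plot_id), function(df) {
      pid <- as.character(df$plot_id[1])
      area <- if (!is.null(areas) && pid %in% names(areas)) areas[[pid]]
              else if ("plot_area_ha" %in% names(df)) df$plot_area_ha[1]
              else abort("no plot area for plot %s", pid)
      d <- plot_dynamics(df, plot_area = area,
                         std_exponent = config$std_exponent %||% 0.08)
      data.frame(plot_id = pid, monitoring_years = d$monitoring_years,
                 agb_start = d$agb_start, agb_end = d$agb_end,
                 agb_tw_mean = d$agb_tw_mean, dagb_abs = d$dagb_abs,
                 agwp = d$agwp, agb_mort = d$agb_mort,
                 stem_mort_rate = d$stem_mort_rate,
                 stem_mort_rate_std = d$stem_mort_rate_std,
                 tau_w = d$tau_w, dagb_rel = d$dagb_rel,
                 agwp_rel = d$agwp_rel, agb_mort_rel = d$agb_mort_rel)
    }))
  })
  .write_out(dynamics, file.path(out_dir, "plot_dynamics.csv"))

  # 5. community-weighted means (hydraulics + any extra traits supplied)
  cwm_table <- stage("cwm", {
    ab <- read_table(config$abundance, "abundance")
    tr <- hydraulics
    if (!is.null(config$traits)) {
      extra <- read_table(config$traits, "traits")
      tr <- merge(tr, extra, by = c("species", "site"), all = TRUE,
                  suffixes = c("", ".extra"))
    }
    tr <- merge(tr, ab, by = c("species", "site"))
    trait_cols <- intersect(c("psi50", "psi88", "psi_dry", "hsm50", "hsm88",
                              "lma", "wd_stem", "wd_branch"), names(tr))
    do.call(rbind, lapply(split(tr, tr$site), function(df) {
      row <- data.frame(site = df$site[1])
      for (v in trait_cols) {
        res <- tryCatch(cwm(df[[v]], df$basal_area), error = function(e) NULL)
        row[[v]] <- if (is.null(res)) NA_real_ else res$cwm
        row[[paste0("coverage_", v)]] <- if (is.null(res)) NA_real_ else res$coverage
      }
      row
    }))
  })
  .write_out(cwm_table, file.path(out_dir, "cwm.csv"))

  # 6. predictor screen of relative net biomass change
  screen <- stage("regress", {
    site_map <- config$plot_site %||%
      stats::setNames(dynamics$plot_id, dynamics$plot_id)
    dynamics$site <- site_map[as.character(dynamics$plot_id)]
    tab <- merge(merge(dynamics, clim_sum, by = "site"), cwm_table, by = "site")
    preds <- intersect(c("mat", "map", "mcwd", "psi50", "psi_dry", "hsm50",
                         "wd_stem", "wd_branch", "lma"), names(tab))
    if (nrow(tab) >= 4) {
      predictor_screen(tab, "dagb_rel", preds,
                       m = config$bonferroni_m %||% length(preds))
    } else NULL
  })
  if (!is.null(screen)) .write_out(screen, file.path(out_dir, "predictor_screen.csv"))

  manifest <- list(
    config = config[setdiff(names(config), "mat")],
    rows = list(curve_fits = nrow(curves), species_hydraulics = nrow(hydraulics),
                climate_summary = nrow(clim_sum), plot_dynamics = nrow(dynamics),
                cwm = nrow(cwm_table),
                predictor_screen = if (is.null(screen)) 0 else nrow(screen)),
    warnings = warnings_log,
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)

  invisible(list(curve_fits = curves, species_hydraulics = hydraulics,
                 climate_summary = clim_sum, plot_dynamics = dynamics,
                 cwm = cwm_table, predictor_screen = screen,
                 manifest = manifest))
}
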