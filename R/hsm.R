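# Hydraulic safety margins from dry-season midday leaf water potentials.

#' Individual dry-season water potential
#'
#' Arithmetic mean of the midday leaf water potentials of one individual at
#' the peak of the dry season. Field protocols sample leaves between 11:00
#' and 14:30; values with times outside that window are retained with a
#' warning, since the window is a protocol recommendation rather than a
#' filter on deposited data.
#'
#' @param leaf_values numeric vector of leaf water potentials (MPa, <= 0).
#' @param sample_time optional clock times ("HH:MM" strings or decimal
#'   hours), one per leaf or a single value for all.
#' @return Mean water potential (MPa).
#' @export
individual_psi_dry <- function(leaf_values, sample_time = NULL) {
  leaf_values <- leaf_values[!is.na(leaf_values)]
  if (!length(leaf_values)) abort("no leaf water potential values supplied")
  if (any(leaf_values > 0)) abort("leaf water potentials must be <= 0 MPa")
  if (!is.null(sample_time)) {
    mins <- parse_clock_minutes(sample_time)
    out <- !is.na(mins) & (mins < 11 * 60 | mins > 14 * 60 + 30)
    if (any(out)) {
      warnf("%d sampling time(s) outside the 11:00-14:30 midday window; values retained",
            sum(out))
    }
  }
  mean(leaf_values)
}

#' Species-level dry-season water potential
#'
#' Aggregates individual means to a species value. The default takes the
#' minimum (most negative) individual mean, i.e. the strongest water stress
#' observed for the species; `"mean"` is available for sensitivity analyses.
#'
#' @param individual_means numeric vector of per-individual mean potentials
#'   (MPa), one entry per individual of a single species.
#' @param aggregation `"min"` (default) or `"mean"`.
#' @param species optional species labels used only to verify that a single
#'   species was supplied.
#' @return Species psi_dry (MPa).
#' @export
species_psi_dry <- function(individual_means, aggregation = c("min", "mean"),
                            species = NULL) {
  aggregation <- match.arg(aggregation)
  if (!is.null(species) && length(unique(species)) > 1) {
    abort("species_psi_dry expects individuals of a single species, got: %s",
          paste(unique(species), collapse = ", "))
  }
  individual_means <- individual_means[!is.na(individual_means)]
  if (!length(individual_means)) abort("no individual psi_dry values supplied")
  if (aggregation == "min") min(individual_means) else mean(individual_means)
}

#' Hydraulic safety margins
#'
#' `hsm50 = psi_dry - psi50` and `hsm88 = psi_dry - psi88`. Negative margins
#' are meaningful: they indicate that trees seasonally cross the embolism
#' threshold. Since `psi88 < psi50`, `hsm88 > hsm50` always holds.
#'
#' @param psi_dry species dry-season leaf water potential (MPa).
#' @param psi50,psi88 embolism thresholds (MPa); `psi88` may be `NA` if only
#'   hsm50 is required. Vectorized over all arguments.
#' @return A data frame with columns `hsm50` and `hsm88`.
#' @export
compute_hsm <- function(psi_dry, psi50, psi88 = NA_real_) {
  n <- max(length(psi_dry), length(psi50), length(psi88))
  psi_dry <- rep_len(psi_dry, n)
  psi50 <- rep_len(psi50, n)
  psi88 <- rep_len(psi88, n)
  bad <- !is.na(psi88) & psi88 >= psi50
  if (any(bad)) abort("psi88 must be more negative than psi50")
  data.frame(hsm50 = psi_dry - psi50, hsm88 = psi_dry - psi88)
}

#' Build a species-by-site hydraulics table
#'
#' Joins per-leaf midday water potential records with fitted curve
#' parameters into the species hydraulics table consumed by community-level
#' analyses.
#'
#' @param potentials data frame with columns `species`, `site`,
#'   `individual_id`, `leaf_psi_mpa` and optionally `time`.
#' @param fits data frame with columns `species`, `site`, `psi50`, `psi88`.
#' @param aggregation species aggregation passed to [species_psi_dry()].
#' @return Data frame: `species`, `site`, `psi50`, `psi88`, `psi_dry`,
#'   `hsm50`, `hsm88`.
#' @export
species_hydraulics <- function(potentials, fits, aggregation = "min") {
  check_columns(potentials, c("species", "site", "individual_id", "leaf_psi_mpa"),
                "potentials table")
  check_columns(fits, c("species", "site", "psi50", "psi88"), "curve-fit table")
  key <- interaction(potentials$species, potentials$site, drop = TRUE)
  psi_dry <- vapply(split(potentials, key), function(df) {
    ind <- vapply(split(df, df$individual_id), function(d) {
      individual_psi_dry(d$leaf_psi_mpa, d$time %||% NULL)
    }, 0)
    species_psi_dry(ind, aggregation = aggregation)
  }, 0)
  first <- !duplicated(key)
  dry <- data.frame(species = potentials$species[first],
                    site = potentials$site[first],
                    psi_dry = psi_dry[as.character(key[first])])
  out <- merge(fits[, c("species", "site", "psi50", "psi88")], dry,
               by = c("species", "site"))
  if (!nrow(out)) abort("no species x site overlap between potentials and fits")
  hs <- compute_hsm(out$psi_dry, out$psi50, out$psi88)
  out$hsm50 <- hs$hsm50
  out$hsm88 <- hs$hsm88
  out[order(out$site, out$species), ]
}
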