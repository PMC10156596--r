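# Tree-level allometry: height from diameter, biomass from diameter,
# wood density and height.

#' Allometry configuration
#'
#' Parameters for the moist-forest biomass model `AGB = k * wd * dbh^2 * H`
#' (kg, with wood density in g cm^-3, diameter in cm and height in m) and
#' the Weibull height model `H = a * (1 - exp(-b * dbh^c))`. Defaults follow
#' the widely used moist-forest coefficient (k = 0.0509) and a pan-Amazon
#' Weibull parameterization; regional analyses should set their own
#' coefficients explicitly.
#'
#' @param agb_k multiplier of the biomass model (default 0.0509).
#' @param weibull_a asymptotic height (m).
#' @param weibull_b,weibull_c shape parameters of the height model.
#' @return A list of class `allometry_config`.
#' @export
allometry_config <- function(agb_k = 0.0509, weibull_a = 42.574,
                             weibull_b = 0.0482, weibull_c = 0.8307) {
  check_number(agb_k, "agb_k", lower = 0, strict_lower = TRUE)
  check_number(weibull_a, "weibull_a", lower = 0, strict_lower = TRUE)
  check_number(weibull_b, "weibull_b", lower = 0, strict_lower = TRUE)
  check_number(weibull_c, "weibull_c", lower = 0, strict_lower = TRUE)
  structure(list(agb_k = agb_k, weibull_a = weibull_a,
                 weibull_b = weibull_b, weibull_c = weibull_c),
            class = "allometry_config")
}

#' Estimate tree height from diameter
#'
#' Weibull height model `H = a * (1 - exp(-b * dbh^c))`: monotone increasing
#' in diameter with asymptote `a`.
#'
#' @param dbh diameter at breast height (cm, >= 0), vectorized.
#' @param cfg an [allometry_config()].
#' @return Height in m.
#' @export
tree_height <- function(dbh, cfg = allometry_config()) {
  if (any(dbh < 0, na.rm = TRUE)) abort("dbh must be >= 0")
  cfg$weibull_a * (1 - exp(-cfg$weibull_b * dbh^cfg$weibull_c))
}

#' Estimate tree aboveground biomass
#'
#' Moist-forest allometry `AGB = k * wd * dbh^2 * height` (kg): linear in
#' wood density and height, quadratic in diameter.
#'
#' @param dbh diameter at breast height (cm).
#' @param wd wood density (g cm^-3).
#' @param height tree height (m); computed from `dbh` via [tree_height()]
#'   when `NULL`.
#' @param cfg an [allometry_config()].
#' @return Biomass in kg.
#' @export
tree_agb <- function(dbh, wd, height = NULL, cfg = allometry_config()) {
  if (is.null(height)) height <- tree_height(dbh, cfg)
  cfg$agb_k * wd * dbh^2 * height
}
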