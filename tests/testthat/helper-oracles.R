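# Independent oracles used across test files.

# brute-force grid search of the sigmoid SSE surface; intentionally
# independent of the package optimizer
grid_search_sse <- function(psi, pad,
                            p50_grid = seq(-10, -0.05, by = 0.005),
                            s_grid = seq(1, 300, by = 0.25)) {
  D <- outer(-p50_grid, psi, "+")  # [i, j] = psi_j - p50_i
  padm <- matrix(pad, nrow = length(p50_grid), ncol = length(psi), byrow = TRUE)
  best_sse <- Inf
  best_par <- c(NA, NA)
  for (s in s_grid) {
    sse <- rowSums((padm - 100 / (1 + exp((s / 25) * D)))^2)
    i <- which.min(sse)
    if (sse[i] < best_sse) {
      best_sse <- sse[i]
      best_par <- c(p50_grid[i], s)
    }
  }
  list(par = best_par, sse = best_sse)
}

# invert the moist-forest allometry for the diameter giving a target AGB at
# fixed wood density (used to build hand-valued toy censuses)
dbh_for_agb <- function(agb_kg, wd, cfg = allometry_config()) {
  uniroot(function(d) tree_agb(d, wd, cfg = cfg) - agb_kg,
          c(1, 300), tol = 1e-12)$root
}

# single-plot toy census in long format from a compact spec:
# trees = list(list(id, wd, dbh = c(dbh at each census or NA once dead)))
build_census <- function(trees, dates, plot_id = "toy") {
  rows <- list()
  for (tr in trees) {
    present <- which(!is.na(tr$dbh))
    for (k in present) {
      rows[[length(rows) + 1]] <- data.frame(
        plot_id = plot_id, tree_id = tr$id, species = tr$species %||% "sp1",
        wood_density = tr$wd, census_date = dates[k], dbh = tr$dbh[k],
        status = tr$status[k])
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
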