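# Community-weighted traits, water-deficit affiliation, and cross-site
# statistics (standardized major axis regression, group contrasts,
# multiple-testing correction, predictor screening).

#' Basal area of a set of stems
#'
#' `sum(pi * (dbh / 200)^2)` in m^2 for diameters in cm.
#'
#' @param dbh stem diameters (cm).
#' @return Basal area in m^2 (0 for an empty vector).
#' @export
basal_area <- function(dbh) {
  dbh <- dbh[!is.na(dbh)]
  sum(pi * (dbh / 200)^2)
}

#' Basal-area weighted community mean of a trait
#'
#' `sum(w * t) / sum(w)` over the species that have trait data, together
#' with the coverage: the fraction of total weight (community basal area)
#' carried by species with data. Low coverage (sparsely sampled hyperdiverse
#' stands can sit near 14%) triggers a warning, not exclusion.
#'
#' @param trait species trait values (NA = no data).
#' @param weight species weights (basal area), aligned with `trait`.
#' @param coverage_warn warn when coverage falls below this fraction.
#' @return List with `cwm` and `coverage`.
#' @export
cwm <- function(trait, weight, coverage_warn = 0.14) {
  if (length(trait) != length(weight)) abort("trait and weight lengths differ")
  ok <- !is.na(trait) & !is.na(weight)
  if (!any(ok)) abort("no species with both trait and weight data")
  total <- sum(weight[!is.na(weight)])
  coverage <- sum(weight[ok]) / total
  if (coverage < coverage_warn) {
    warnf("trait coverage %.1f%% of basal area is below %.0f%%",
          100 * coverage, 100 * coverage_warn)
  }
  list(cwm = sum(weight[ok] * trait[ok]) / sum(weight[ok]), coverage = coverage)
}

#' Water-deficit affiliation of a species
#'
#' Abundance-weighted mean climatological water deficit of the plots in
#' which the species occurs: `sum(a * cwd) / sum(a)`. More negative values
#' indicate dry-affiliated species.
#'
#' @param abundance relative abundance of the species in each plot (>= 0,
#'   not all zero).
#' @param plot_cwd climatological water deficit of each plot (mm, <= 0).
#' @return WDA in mm.
#' @export
wda <- function(abundance, plot_cwd) {
  if (length(abundance) != length(plot_cwd)) abort("abundance and plot_cwd lengths differ")
  if (all(abundance == 0)) abort("all abundances are zero")
  sum(abundance * plot_cwd) / sum(abundance)
}

#' Standardized major axis regression
#'
#' Symmetric line fitting: `slope = sign(r) * sd(y) / sd(x)` and
#' `intercept = mean(y) - slope * mean(x)`. The p-value is that of the
#' Pearson correlation test (the SMA slope differs from zero exactly when
#' the correlation does), and confidence intervals are percentile bootstrap
#' over resampled (x, y) pairs.
#'
#' @param x,y paired observations (n >= 3, both with positive variance).
#' @param bootstrap_n bootstrap resamples (default 1000; 0 disables).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return An object of class `sma_fit`: `slope`, `intercept`, `r2`,
#'   `p_value`, `ci_slope`, `ci_intercept`, `n`, `method`.
#' @export
sma_fit <- function(x, y, bootstrap_n = 1000, seed = NULL, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("x and y must both vary")
  point <- function(x, y) {
    r <- stats::cor(x, y)
    sl <- ifelse(r < 0, -1, 1) * stats::sd(y) / stats::sd(x)  # r = 0: positive
    c(slope = sl, intercept = mean(y) - sl * mean(x), r = r)
  }
  est <- point(x, y)
  p <- stats::cor.test(x, y)$p.value
  ci_slope <- ci_int <- c(NA_real_, NA_real_)
  if (bootstrap_n > 0) {
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    draws <- with_seed(seed, {
      m <- matrix(NA_real_, bootstrap_n, 2)
      for (b in seq_len(bootstrap_n)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) next
        pb <- point(x[idx], y[idx])
        m[b, ] <- pb[1:2]
      }
      m
    })
    ok_b <- stats::complete.cases(draws)
    if (sum(ok_b) >= 10) {
      ci_slope <- unname(stats::quantile(draws[ok_b, 1], probs))
      ci_int <- unname(stats::quantile(draws[ok_b, 2], probs))
    }
  }
  structure(list(slope = unname(est["slope"]), intercept = unname(est["intercept"]),
                 r2 = unname(est["r"])^2, p_value = p,
                 ci_slope = ci_slope, ci_intercept = ci_int,
                 n = n, method = "sma"),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("%s regression (n = %d)\n", toupper(x$method), x$n))
  cat(sprintf("  slope %.4g [%.4g, %.4g], intercept %.4g [%.4g, %.4g]\n",
              x$slope, x$ci_slope[1], x$ci_slope[2],
              x$intercept, x$ci_intercept[1], x$ci_intercept[2]))
  cat(sprintf("  R2 = %.3f, p = %.4g\n", x$r2, x$p_value))
  invisible(x)
}

#' Ordinary least squares fit
#'
#' Standard linear regression of y on x, returned in the same structure as
#' [sma_fit()] for interchangeable reporting.
#'
#' @inheritParams sma_fit
#' @return An object of class `sma_fit` with `method = "ols"`.
#' @export
ols_r2 <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (stats::sd(x) == 0) abort("x must vary")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared, p_value = p,
                 ci_slope = c(NA_real_, NA_real_),
                 ci_intercept = c(NA_real_, NA_real_),
                 n = length(x), method = "ols"),
            class = "sma_fit")
}

#' Rank-based group contrasts
#'
#' Omnibus Kruskal-Wallis test across groups followed by pairwise two-sided
#' Wilcoxon rank-sum tests (exact for small tie-free samples, tie-corrected
#' normal approximation otherwise), delegated to the standard `stats`
#' implementations. Groups with fewer than two values are dropped with a
#' warning.
#'
#' @param values numeric observations.
#' @param groups group labels aligned with `values`.
#' @param design `"kw_then_pairwise"` (default) or `"pairwise"` (skip the
#'   omnibus test).
#' @return List with `omnibus` (`statistic`, `p_value`, `df`; NULL when
#'   skipped) and `pairwise` (data frame `group1`, `group2`, `p_value`).
#' @export
group_contrasts <- function(values, groups, design = c("kw_then_pairwise", "pairwise")) {
  design <- match.arg(design)
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warnf("dropping group(s) with fewer than 2 values: %s",
          paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  lev <- unique(groups)
  if (length(lev) < 2) abort("need at least 2 groups with n >= 2")
  omnibus <- NULL
  if (design == "kw_then_pairwise") {
    kw <- stats::kruskal.test(values, factor(groups))
    omnibus <- list(statistic = unname(kw$statistic), p_value = kw$p.value,
                    df = unname(kw$parameter))
  }
  pairs <- utils::combn(lev, 2)
  pw <- apply(pairs, 2, function(pr) {
    w <- suppressWarnings(stats::wilcox.test(values[groups == pr[1]],
                                             values[groups == pr[2]],
                                             alternative = "two.sided"))
    data.frame(group1 = pr[1], group2 = pr[2], p_value = w$p.value)
  })
  list(omnibus = omnibus, pairwise = do.call(rbind, pw))
}

#' Bonferroni correction
#'
#' `min(1, p * m)` for each p-value, with `m` the number of tests in the
#' family.
#'
#' @param p_values raw p-values.
#' @param m number of tests (default: `length(p_values)`).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < 1) abort("m must be >= 1")
  pmin(1, p_values * m)
}

#' Screen predictors of a plot-level response
#'
#' Fits a bivariate SMA regression of the response on each candidate
#' predictor, Bonferroni-adjusts the p-values over the family of `m` tests,
#' and ranks predictors by variance explained. Missing predictor columns
#' are skipped with a warning.
#'
#' @param data one row per plot/site with the response and predictors.
#' @param response name of the response column (e.g. relative net biomass
#'   change).
#' @param predictors character vector of predictor column names.
#' @param m family size for the Bonferroni correction (default: number of
#'   predictors actually tested).
#' @param alpha significance level for the `significant` flag.
#' @return Data frame sorted by decreasing `r2`: `predictor`, `slope`,
#'   `r2`, `p_raw`, `p_adj`, `significant`, `n`.
#' @export
predictor_screen <- function(data, response, predictors, m = NULL, alpha = 0.05) {
  check_columns(data, response, "screen table")
  have <- predictors %in% names(data)
  if (any(!have)) {
    warnf("skipping missing predictor column(s): %s",
          paste(predictors[!have], collapse = ", "))
  }
  predictors <- predictors[have]
  if (!length(predictors)) abort("no predictor columns available")
  if (sum(stats::complete.cases(data[, c(response, predictors)])) < 4) {
    abort("need at least 4 plots with complete data")
  }
  m <- m %||% length(predictors)
  rows <- lapply(predictors, function(p) {
    fit <- sma_fit(data[[p]], data[[response]], bootstrap_n = 0)
    data.frame(predictor = p, slope = fit$slope, r2 = fit$r2,
               p_raw = fit$p_value, n = fit$n)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p_raw, m)
  out$significant <- out$p_adj < alpha
  out <- out[order(-out$r2), c("predictor", "slope", "r2", "p_raw", "p_adj",
                               "significant", "n")]
  rownames(out) <- NULL
  out
}
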