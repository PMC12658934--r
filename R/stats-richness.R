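#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k+1)/(n-k-1)` for `n > k + 1`, else `Inf`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return The AICc value.
#' @export
aicc_value <- function(loglik, k, n) {
  if (k < 1) stop("k must be >= 1")
  aic <- -2 * loglik + 2 * k
  if (n <= k + 1) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc of a fitted model
#' @param fit A fitted model with `logLik` method, or a `decay_glmm`.
#' @return AICc.
#' @export
aicc <- function(fit) UseMethod("aicc")

#' @export
aicc.default <- function(fit) {
  ll <- stats::logLik(fit)
  aicc_value(as.numeric(ll), attr(ll, "df"), stats::nobs(fit))
}

#' Poisson GLM of species richness
#'
#' Maximum-likelihood Poisson regression with log link, fitted by
#' iteratively reweighted least squares (deviance convergence tolerance
#' 1e-8, at most 100 iterations). Rank-deficient designs error, naming
#' the aliased columns.
#'
#' @param formula Model formula (response must be non-negative counts).
#' @param data Data frame of covariates.
#' @param label Optional model label used in comparison tables.
#' @return A fitted object of class `bee_glm` extending `glm`, with an
#'   `aicc` component.
#' @export
fit_poisson_glm <- function(formula, data, label = NULL) {
  fit <- stats::glm(formula, data = data, family = stats::poisson(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("IRLS did not converge within 100 iterations")
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design; aliased columns: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  fit$label <- if (is.null(label)) deparse(formula) else label
  fit$aicc <- aicc.default(fit)
  class(fit) <- c("bee_glm", class(fit))
  fit
}

#' @export
print.bee_glm <- function(x, digits = 4, ...) {
  cat("Poisson GLM:", x$label, "\n")
  print(round(stats::coef(x), digits))
  cat("logLik ", round(as.numeric(stats::logLik(x)), 2),
      "  AICc ", round(x$aicc, 2), "  n ", stats::nobs(x), "\n", sep = "")
  invisible(x)
}

#' Richness models across radii and LLS types
#'
#' Fits the species-richness Poisson GLM
#' `richness ~ log(LLS_radius + 1) + plant_richness +
#' log(grassland_radius + 1e-4) + country + x + y`
#' for every radius and LLS type (all seminatural, forest only,
#' nonforest), with coordinates centred and scaled for numerical
#' stability (this affects coefficients, not deviances or AICc
#' differences). Lengths enter as `log(m + 1)` and grassland as
#' `log(p + 1e-4)` to guard `log(0)`.
#'
#' @param sites A `site_table` with a `richness` column (bee species
#'   richness per site), or supply `richness` separately.
#' @param metrics Output of [site_landscape_metrics()].
#' @param richness Optional richness vector aligned with `sites$id`.
#' @return List with `fits` (nested list `type -> radius`), `aicc_table`
#'   (radius x type data frame), and `null_aicc`.
#' @export
fit_richness_models <- function(sites, metrics, richness = sites$richness) {
  if (is.null(richness)) stop("supply per-site bee species richness")
  radii <- sort(unique(metrics$radius))
  types <- c(all = "lls_all_m", forest = "lls_forest_m",
             nonforest = "lls_nonforest_m")
  base <- data.frame(id = sites$id, richness = richness,
                     plant_richness = sites$plant_richness,
                     country = factor(sites$country),
                     xs = as.numeric(scale(sites$x)),
                     ys = as.numeric(scale(sites$y)))
  one_country <- length(unique(base$country)) < 2L
  rhs0 <- "plant_richness + log_grass + xs + ys"
  if (!one_country) rhs0 <- paste(rhs0, "+ country")
  fits <- list()
  tab <- data.frame(radius = radii)
  for (ty in names(types)) {
    fits[[ty]] <- list()
    for (rad in radii) {
      mk <- metrics[metrics$radius == rad, ]
      d <- base
      d$log_lls <- log(mk[[types[[ty]]]][match(d$id, mk$site)] + 1)
      d$log_grass <- log(mk$grassland_prop[match(d$id, mk$site)] + 1e-4)
      f <- stats::as.formula(paste("richness ~ log_lls +", rhs0))
      fits[[ty]][[as.character(rad)]] <-
        fit_poisson_glm(f, d, label = paste0(ty, "_", rad, "m"))
    }
    tab[[ty]] <- vapply(fits[[ty]], function(f) f$aicc, numeric(1))
  }
  # null model without any LLS term (same control covariates)
  mk <- metrics[metrics$radius == radii[1], ]
  d <- base
  d$log_grass <- log(mk$grassland_prop[match(d$id, mk$site)] + 1e-4)
  null_fit <- fit_poisson_glm(
    stats::as.formula(paste("richness ~", rhs0)), d, label = "null")
  list(fits = fits, aicc_table = tab, null_fit = null_fit,
       null_aicc = null_fit$aicc)
}

#' Select the best radius per LLS type by AICc
#'
#' @param aicc_table Radius x type AICc data frame (first column
#'   `radius`), as returned by [fit_richness_models()].
#' @return Named list: per type, `list(radius, aicc)`; ties resolve to
#'   the smaller radius.
#' @export
select_radius <- function(aicc_table) {
  types <- setdiff(names(aicc_table), "radius")
  out <- list()
  for (ty in types) {
    i <- which(aicc_table[[ty]] == min(aicc_table[[ty]]))[1]
    out[[ty]] <- list(radius = aicc_table$radius[i],
                      aicc = aicc_table[[ty]][i])
  }
  out
}

#' Likelihood-ratio drop-one test
#'
#' Refits the model without the given term (for an interaction, only the
#' interaction columns are dropped) and reports
#' `LRT = 2 (l_full - l_reduced)` against a chi-squared reference.
#'
#' @param fit A fitted `bee_glm` (or any `glm`).
#' @param term Term label as it appears in the model formula.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
lrt_drop1 <- function(fit, term) {
  tl <- attr(stats::terms(fit), "term.labels")
  if (!term %in% tl)
    stop("term '", term, "' not in the model (terms: ",
         paste(tl, collapse = ", "), ")")
  reduced <- stats::update(fit, stats::as.formula(paste(". ~ . -", term)),
                           data = stats::model.frame(fit))
  stat <- 2 * (as.numeric(stats::logLik(fit)) -
               as.numeric(stats::logLik(reduced)))
  stat <- max(stat, 0)
  df <- attr(stats::logLik(fit), "df") - attr(stats::logLik(reduced), "df")
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Moran's I test on model residuals
#'
#' Spatial autocorrelation of (Pearson) residuals with inverse-distance,
#' row-normalized weights and zero diagonal; expectation `-1/(n-1)`
#' under spatial randomness, two-sided normal-approximation p-value.
#'
#' @param residuals Residual vector.
#' @param coords Two-column matrix of site coordinates (metres).
#' @return List with `observed`, `expected`, `sd`, `p.value`.
#' @export
morans_i <- function(residuals, coords) {
  coords <- matrix(as.numeric(coords), ncol = 2)
  n <- length(residuals)
  if (n < 3L) stop("need at least 3 points")
  if (stats::sd(residuals) == 0) stop("residuals are constant")
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0)) stop("coincident points give infinite weights")
  w <- 1 / d
  diag(w) <- 0
  w <- w / rowSums(w)
  res <- ape::Moran.I(residuals, w, alternative = "two.sided")
  list(observed = res$observed, expected = res$expected,
       sd = res$sd, p.value = res$p.value)
}

#' Pearson dispersion check for a Poisson fit
#'
#' Ratio of the Pearson chi-squared statistic to its residual degrees of
#' freedom; values well above 1 indicate overdispersion.
#'
#' @param fit A fitted Poisson `glm`.
#' @param flag_above Overdispersion flag threshold (default 1.5).
#' @return List with `ratio` and logical `overdispersed`.
#' @export
dispersion_check <- function(fit, flag_above = 1.5) {
  pr <- stats::residuals(fit, type = "pearson")
  ratio <- sum(pr^2) / stats::df.residual(fit)
  if (stats::df.residual(fit) == 0) ratio <- 0
  list(ratio = ratio, overdispersed = is.finite(ratio) && ratio > flag_above)
}
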