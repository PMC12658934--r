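#' Crossed-random-intercept model of pairwise compositional similarity
#'
#' Fits `similarity ~ distance + plantSR_i * plantSR_j + sim_plants +
#' (1 | site_i) + (1 | site_j)` by maximum likelihood, with a Gaussian or
#' Student-t response. The two crossed random intercepts absorb
#' site-specific differences in average similarity to other sites; the
#' plant covariates control for habitat-quality confounding. With
#' `distance = NULL` the distance term is omitted (the null model).
#'
#' The parameter count used for AICc is the fitted object's full count:
#' fixed effects + 2 random-intercept variances + the residual scale,
#' plus the Student-t degrees of freedom when that family is used.
#'
#' @param pairs Pair table from [build_pair_table()].
#' @param response Response column name (e.g. `"sim_all"`).
#' @param distance Distance column name, or `NULL` for the null model.
#' @param family `"gaussian"` or `"student_t"`.
#' @param quadratic Also include the squared distance term?
#' @param label Optional model label.
#' @return Object of class `decay_glmm`.
#' @export
fit_crossed_glmm <- function(pairs, response, distance = NULL,
                             family = c("gaussian", "student_t"),
                             quadratic = FALSE, label = NULL) {
  family <- match.arg(family)
  d <- pairs
  d <- d[!is.na(d[[response]]), , drop = FALSE]
  n_dropped <- nrow(pairs) - nrow(d)
  if (n_dropped > 0)
    message(n_dropped, " pair(s) with undefined similarity dropped")
  d$..y <- d[[response]]
  d$site_i <- factor(d$site_i); d$site_j <- factor(d$site_j)
  rhs <- "plantSR_i * plantSR_j + sim_plants"
  has_covars <- all(c("plantSR_i", "plantSR_j", "sim_plants") %in% names(d))
  if (!has_covars) rhs <- "1"
  if (!is.null(distance)) {
    d$..dist <- d[[distance]]
    # orthogonal polynomial: well conditioned at km scales
    dterm <- if (quadratic) "stats::poly(..dist, 2)" else "..dist"
    rhs <- paste(dterm, "+", rhs)
  }
  f <- stats::as.formula(paste("..y ~", rhs, "+ (1 | site_i) + (1 | site_j)"))
  fam <- if (family == "gaussian") stats::gaussian()
         else glmmTMB::t_family()
  fit <- suppressWarnings(
    glmmTMB::glmmTMB(f, data = d, family = fam, REML = FALSE))
  if (is.null(fit$fit) || anyNA(glmmTMB::fixef(fit)$cond) ||
      !is.finite(fit$fit$objective))
    stop("GLMM fitting failed (objective ",
         signif(fit$fit$objective, 3), ")")
  conv <- fit$fit$convergence == 0
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  # a boundary fit (variance at 0, non-PD Hessian) reports NA logLik even
  # though the maximized objective is valid; recover the ML value
  hessian_ok <- !is.na(as.numeric(ll))
  if (!hessian_ok) ll <- structure(-fit$fit$objective, df = k, class = "logLik")
  n <- stats::nobs(fit)
  vc <- glmmTMB::VarCorr(fit)$cond
  vars <- c(site_i = unname(attr(vc$site_i, "stddev"))^2,
            site_j = unname(attr(vc$site_j, "stddev"))^2)
  structure(list(
    model = fit,
    label = if (is.null(label)) paste0(response, " ~ ",
                                       if (is.null(distance)) "null"
                                       else distance) else label,
    family = family,
    response = response,
    distance = distance,
    coefficients = glmmTMB::fixef(fit)$cond,
    ranef_var = vars,
    sigma = stats::sigma(fit),
    t_df = if (family == "student_t")
      unname(glmmTMB::family_params(fit)) else NA_real_,
    loglik = as.numeric(ll), k = k, n = n,
    aic = -2 * as.numeric(ll) + 2 * k,
    aicc = aicc_value(as.numeric(ll), k, n),
    converged = conv, hessian_ok = hessian_ok,
    boundary_variance = any(vars < 1e-10)), class = "decay_glmm")
}

#' @export
print.decay_glmm <- function(x, digits = 4, ...) {
  cat("Crossed-intercept GLMM (", x$family, "): ", x$label, "\n", sep = "")
  print(round(x$coefficients, digits))
  cat("random-intercept variances: site_i ", signif(x$ranef_var[1], 3),
      ", site_j ", signif(x$ranef_var[2], 3), "\n", sep = "")
  cat("logLik ", round(x$loglik, 2), "  k ", x$k, "  n ", x$n,
      "  AICc ", round(x$aicc, 2), "\n", sep = "")
  if (!x$converged) cat("note: optimizer reported non-convergence\n")
  if (x$boundary_variance) cat("note: a variance component is at zero\n")
  invisible(x)
}

#' @export
coef.decay_glmm <- function(object, ...) object$coefficients

#' @export
logLik.decay_glmm <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
aicc.decay_glmm <- function(fit) fit$aicc

#' @export
summary.decay_glmm <- function(object, ...) summary(object$model, ...)

#' Likelihood-ratio test of the distance term in a decay model
#'
#' @param fit A `decay_glmm` with a distance term.
#' @param pairs The pair table the model was fitted on.
#' @return List with `statistic`, `df`, `p.value`, and the Wald `z` of
#'   the distance coefficient.
#' @export
lrt_distance <- function(fit, pairs) {
  if (is.null(fit$distance)) stop("model has no distance term")
  null <- fit_crossed_glmm(pairs, fit$response, distance = NULL,
                           family = fit$family)
  stat <- max(2 * (fit$loglik - null$loglik), 0)
  df <- fit$k - null$k
  sm <- summary(fit$model)$coefficients$cond
  z <- sm["..dist", "z value"]
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE), z = z)
}

#' Compare distance measures by AICc
#'
#' Fits, per country, the crossed-intercept similarity model with each
#' candidate distance measure plus the null model without any distance,
#' and tabulates AICc and the AICc difference relative to the
#' geographic-distance model (positive `delta_vs_geo` = better than
#' geographic distance).
#'
#' @param pairs Pair table (with distance columns).
#' @param response Response column name.
#' @param distances Named character vector of distance columns; the one
#'   named `"geographic"` is the reference.
#' @param family Response family, see [fit_crossed_glmm()].
#' @param by_country Fit each country separately (default) or pooled.
#' @return Data frame: country, model, aicc, delta_vs_geo, plus the
#'   fitted objects in `attr(, "fits")`.
#' @export
compare_distance_models <- function(
    pairs, response,
    distances = c(geographic = "geo_km",
                  lcp_length_lls = "lcp_len_lls_km",
                  lcp_length_forest = "lcp_len_forest_km",
                  lcp_cost_lls = "lcp_cost_lls",
                  lcp_cost_forest = "lcp_cost_forest"),
    family = "gaussian", by_country = TRUE) {
  stopifnot("geographic" %in% names(distances))
  groups <- if (by_country) split(pairs, pairs$country) else list(all = pairs)
  rows <- list(); fits <- list()
  for (ct in names(groups)) {
    g <- groups[[ct]]
    safe_fit <- function(dist) tryCatch(
      fit_crossed_glmm(g, response, dist, family),
      error = function(e) NULL)
    ms <- list(null = safe_fit(NULL))
    for (nm in names(distances)) ms[[nm]] <- safe_fit(distances[[nm]])
    a <- vapply(ms, function(m) if (is.null(m)) NA_real_ else m$aicc,
                numeric(1))
    rows[[ct]] <- data.frame(country = ct, model = names(ms), aicc = a,
                             delta_vs_geo = a["geographic"] - a,
                             row.names = NULL)
    fits[[ct]] <- ms
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "fits") <- fits
  out
}

#' Maximum-distance sensitivity analysis
#'
#' For each distance threshold (10–105 km in 5-km steps by default) the
#' similarity-by-distance relationship is fitted twice on the pairs
#' below the threshold — untransformed distance versus a second-order
#' polynomial — and `delta_aicc = AICc(linear) - AICc(quadratic)` is
#' recorded (negative values favour the untransformed model). The chosen
#' maximum distance is the largest threshold at which the linear model
#' performs best (`delta_aicc < 0`) or indistinguishably
#' (`|delta_aicc| < 2`), keeping as much data as possible while the
#' decay is monotone. Thresholds with fewer than `min_pairs` pairs are
#' skipped.
#'
#' @param pairs Pair table.
#' @param response Response column name.
#' @param distance Distance column used for thresholding and modelling.
#' @param thresholds Threshold grid in km.
#' @param family Response family.
#' @param min_pairs Minimum pairs per threshold (default 30).
#' @param by_country Analyze each country separately (default) or pooled.
#' @return Object of class `decay_sensitivity`: per-country table of
#'   `threshold_km`, `n`, `delta_aicc`, and `chosen_km`.
#' @export
threshold_sensitivity <- function(pairs, response, distance = "geo_km",
                                  thresholds = seq(10, 105, by = 5),
                                  family = "gaussian", min_pairs = 30,
                                  by_country = TRUE) {
  groups <- if (by_country) split(pairs, pairs$country) else list(all = pairs)
  res <- list()
  for (ct in names(groups)) {
    g <- groups[[ct]]
    tab <- data.frame(threshold_km = thresholds, n = NA_integer_,
                      delta_aicc = NA_real_, skipped = FALSE)
    for (k in seq_along(thresholds)) {
      sub <- g[!is.na(g[[distance]]) & g[[distance]] <= thresholds[k], ,
               drop = FALSE]
      tab$n[k] <- nrow(sub)
      if (nrow(sub) < min_pairs) { tab$skipped[k] <- TRUE; next }
      if (k > 1L && !tab$skipped[k - 1L] && tab$n[k] == tab$n[k - 1L]) {
        tab$delta_aicc[k] <- tab$delta_aicc[k - 1L]  # identical subset
        next
      }
      lin <- fit_crossed_glmm(sub, response, distance, family,
                              quadratic = FALSE)
      qua <- fit_crossed_glmm(sub, response, distance, family,
                              quadratic = TRUE)
      tab$delta_aicc[k] <- lin$aicc - qua$aicc
    }
    keep <- !tab$skipped &
      (tab$delta_aicc < 0 | abs(tab$delta_aicc) < 2)
    chosen <- if (any(keep, na.rm = TRUE))
      max(tab$threshold_km[which(keep)]) else NA_real_
    res[[ct]] <- list(table = tab, chosen_km = chosen)
  }
  structure(list(per_country = res, response = response,
                 distance = distance), class = "decay_sensitivity")
}

#' @export
print.decay_sensitivity <- function(x, ...) {
  cat("Distance-threshold sensitivity (", x$response, " vs ", x$distance,
      ")\n", sep = "")
  for (ct in names(x$per_country)) {
    r <- x$per_country[[ct]]
    nsk <- sum(r$table$skipped)
    cat("  ", ct, ": chosen max distance ", r$chosen_km, " km",
        if (nsk) paste0(" (", nsk, " thresholds skipped)"), "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.decay_sensitivity <- function(x, ...) {
  ctys <- names(x$per_country)
  graphics::par(mfrow = c(1, length(ctys)))
  for (ct in ctys) {
    r <- x$per_country[[ct]]
    graphics::plot(r$table$threshold_km, r$table$delta_aicc, type = "b",
                   xlab = "max distance (km)",
                   ylab = expression(Delta * AICc ~ (linear - quadratic)),
                   main = ct, ...)
    graphics::abline(h = c(-2, 0, 2), lty = c(3, 1, 3), col = "grey40")
    if (!is.na(r$chosen_km))
      graphics::abline(v = r$chosen_km, col = "red3", lty = 2)
  }
  invisible(x)
}

#' Choose the response family by AICc
#'
#' Fits the geographic-distance model under the Gaussian and Student-t
#' families and returns the family with the lower AICc (a pragmatic
#' counterpart to residual-based family checks).
#'
#' @param pairs Pair table.
#' @param response Response column.
#' @param distance Distance column used for the probe fit.
#' @return `"gaussian"` or `"student_t"`.
#' @export
choose_family <- function(pairs, response, distance = "geo_km") {
  g <- try(fit_crossed_glmm(pairs, response, distance, "gaussian"),
           silent = TRUE)
  t <- try(fit_crossed_glmm(pairs, response, distance, "student_t"),
           silent = TRUE)
  if (inherits(t, "try-error") || !t$converged) return("gaussian")
  if (inherits(g, "try-error")) return("student_t")
  if (t$aicc < g$aicc) "student_t" else "gaussian"
}
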