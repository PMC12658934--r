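#' Validate pipeline inputs
#'
#' Checks a scenario bundle (or equivalently assembled inputs) for the
#' conditions the pipeline assumes: metric-looking coordinates, sites
#' inside the raster, complete trait coverage, unique site ids. Returns
#' issues instead of raising.
#'
#' @param bundle A `scenario_bundle` or list with `grid`, `sites`,
#'   `occ_bees`, `occ_plants`, `traits`.
#' @return Character vector of issues; empty when everything passes.
#' @export
validate_inputs <- function(bundle) {
  issues <- character(0)
  s <- bundle$sites; g <- bundle$grid
  if (anyDuplicated(s$id))
    issues <- c(issues, "duplicate site ids")
  ext <- c(ncol(g$values), nrow(g$values)) * g$cell_size
  out <- s$x < g$origin[1] | s$x > g$origin[1] + ext[1] |
    s$y < g$origin[2] | s$y > g$origin[2] + ext[2]
  if (any(out))
    issues <- c(issues, paste("site(s) outside raster:",
                              paste(s$id[out], collapse = ", ")))
  if (max(abs(c(s$x, s$y))) < 360)
    issues <- c(issues,
                "coordinates look like degrees, not projected metres")
  miss <- setdiff(colnames(bundle$occ_bees), bundle$traits$species)
  if (length(miss))
    issues <- c(issues, paste("species missing trait rows:",
                              paste(miss, collapse = ", ")))
  occ_sites <- rownames(bundle$occ_bees)
  miss2 <- setdiff(s$id, occ_sites)
  if (length(miss2))
    issues <- c(issues, paste("site(s) missing from bee occurrences:",
                              paste(miss2, collapse = ", ")))
  issues
}

#' Run the full connectivity analysis
#'
#' Sequences the whole pipeline on a scenario bundle: boundary
#' extraction (all seminatural and forest-only), per-site landscape
#' metrics, Poisson richness models across radii with AICc radius
#' selection, Moran's I and dispersion diagnostics, LRT of the LLS term;
#' conductance surfaces and least-cost corridors, the pairwise
#' similarity table, the distance-threshold sensitivity analysis, and
#' the AICc comparison of distance measures for all-bee and
#' solitary-bee similarity per country.
#'
#' @param bundle A `scenario_bundle` (or equivalent input list).
#' @param radii Radii (m) for the landscape metrics.
#' @param family `"gaussian"`, `"student_t"`, or `"auto"` (choose by
#'   AICc on a probe fit).
#' @param sensitivity Run the distance-threshold sensitivity analysis
#'   and restrict pairs to the chosen per-country maximum distance?
#' @param eps Conductance floor.
#' @return Object of class `run_report`.
#' @export
run_pipeline <- function(bundle, radii = c(250, 500, 750, 1000, 1250, 1500),
                         family = "auto", sensitivity = TRUE, eps = 1e-6) {
  issues <- validate_inputs(bundle)
  if (length(issues)) stop("stage validate: ", paste(issues, collapse = "; "))
  t0 <- proc.time()[3]
  stage <- function(nm, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage ", nm, ": ", conditionMessage(e), call. = FALSE))
    res
  }
  grid <- bundle$grid; sites <- bundle$sites

  lc <- stage("landcover", {
    lls <- extract_boundaries(grid, seminatural_class_sets(),
                              "all_seminatural")
    forest <- extract_boundaries(grid, list(c(2L, 3L)), "forest")
    list(lls = lls, forest = forest,
         lls_km = total_length(lls) / 1000,
         forest_km = total_length(forest) / 1000,
         nonforest_km = nonforest_length(lls, forest) / 1000)
  })

  metrics <- stage("metrics",
    site_landscape_metrics(sites, lc$lls, lc$forest, grid, radii))

  comm <- stage("community", {
    occ <- curate(bundle$occ_bees, bundle$traits)
    list(occ = occ, richness = site_richness(occ))
  })

  rich <- stage("richness_models", {
    rm <- fit_richness_models(sites, metrics, richness = comm$richness)
    best <- select_radius(rm$aicc_table)
    diag <- lapply(names(best), function(ty) {
      f <- rm$fits[[ty]][[as.character(best[[ty]]$radius)]]
      list(type = ty,
           lrt = lrt_drop1(f, "log_lls"),
           moran = morans_i(stats::residuals(f, type = "pearson"),
                            cbind(sites$x, sites$y)),
           dispersion = dispersion_check(f),
           beta_lls = unname(stats::coef(f)["log_lls"]))
    })
    names(diag) <- names(best)
    c(rm, list(best = best, diagnostics = diag))
  })

  corr <- stage("corridors", {
    fac <- if (!is.null(bundle$cfg)) bundle$cfg$aggregation_factor else 10L
    grids <- list(
      lls = aggregate_proportion(rasterize_lines(lc$lls, grid), fac),
      forest = aggregate_proportion(rasterize_lines(lc$forest, grid), fac))
    pd <- pairwise_distances(sites, grids, eps = eps)
    ratio <- function(col) {
      ok <- pd$geo_km > 0
      pd[[col]][ok] / pd$geo_km[ok]
    }
    list(pairs = pd, grids = grids,
         ratio_lls = ratio("lcp_len_lls_km"),
         ratio_forest = ratio("lcp_len_forest_km"))
  })

  pairs <- stage("similarity",
    build_pair_table(sites, comm$occ, bundle$occ_plants, bundle$traits,
                     corr$pairs))

  sens <- NULL
  if (sensitivity) {
    sens <- stage("sensitivity",
      threshold_sensitivity(pairs, "sim_all", "geo_km"))
    for (ct in names(sens$per_country)) {
      mx <- sens$per_country[[ct]]$chosen_km
      if (!is.na(mx))
        pairs <- pairs[!(pairs$country == ct & pairs$geo_km > mx), ,
                       drop = FALSE]
    }
  }

  if (family == "auto")
    family <- stage("family", choose_family(pairs, "sim_all"))

  decay <- stage("decay", {
    out <- list()
    for (resp in c("sim_all", "sim_solitary")) {
      cmp <- compare_distance_models(pairs, resp, family = family)
      fits <- attr(cmp, "fits")
      best <- lapply(fits, function(ms) {
        a <- vapply(ms, function(m) if (is.null(m)) NA_real_ else m$aicc,
                    numeric(1))
        names(ms)[which.min(a)]
      })
      out[[resp]] <- list(table = cmp, best = best)
    }
    out
  })

  structure(list(
    landcover = lc[c("lls_km", "forest_km", "nonforest_km")],
    metrics = metrics,
    richness = list(aicc_table = rich$aicc_table, best = rich$best,
                    null_aicc = rich$null_aicc,
                    diagnostics = rich$diagnostics),
    corridors = list(
      n_pairs = nrow(corr$pairs),
      ratio_lls_mean = mean(corr$ratio_lls),
      ratio_lls_sd = stats::sd(corr$ratio_lls),
      ratio_forest_mean = mean(corr$ratio_forest),
      ratio_forest_sd = stats::sd(corr$ratio_forest)),
    pairs = pairs,
    sensitivity = sens,
    decay = decay,
    family = family,
    config = list(radii = radii, eps = eps,
                  seed = if (!is.null(bundle$cfg)) bundle$cfg$seed else NA,
                  hash = config_hash(bundle),
                  version = as.character(utils::packageVersion("beecorridors")),
                  elapsed_s = unname(proc.time()[3] - t0))),
    class = "run_report")
}

config_hash <- function(bundle) {
  key <- paste(capture_num(bundle$sites$x), capture_num(bundle$sites$y),
               sum(unclass(bundle$occ_bees)), dim(bundle$grid$values)[1],
               collapse = "|")
  # small rolling hash; stable across runs, no external digest dependency
  v <- utf8ToInt(key)
  sprintf("%08x", Reduce(function(h, ch) (h * 31 + ch) %% 2^28, v, 17L))
}

capture_num <- function(x) paste(signif(x, 10), collapse = ",")

#' @export
print.run_report <- function(x, ...) {
  cat("== Habitat-connectivity run report ==\n")
  cat("Edges: all seminatural ", round(x$landcover$lls_km, 1), " km, forest ",
      round(x$landcover$forest_km, 1), " km, nonforest ",
      round(x$landcover$nonforest_km, 1), " km\n", sep = "")
  cat("Richness models (AICc by radius):\n")
  print(round(as.data.frame(x$richness$aicc_table), 1))
  for (ty in names(x$richness$best)) {
    b <- x$richness$best[[ty]]
    dg <- x$richness$diagnostics[[ty]]
    cat(sprintf(
      "  %s: best radius %d m (AICc %.1f), beta_LLS %.3f, LRT %.2f (p %.3f), Moran p %.3f, dispersion %.2f\n",
      ty, b$radius, b$aicc, dg$beta_lls, dg$lrt$statistic, dg$lrt$p.value,
      dg$moran$p.value, dg$dispersion$ratio))
  }
  cat(sprintf(
    "Corridors: %d within-country pairs; LCP/geo ratio %.2f (lls), %.2f (forest)\n",
    x$corridors$n_pairs, x$corridors$ratio_lls_mean,
    x$corridors$ratio_forest_mean))
  if (!is.null(x$sensitivity)) {
    for (ct in names(x$sensitivity$per_country))
      cat("  max distance ", ct, ": ",
          x$sensitivity$per_country[[ct]]$chosen_km, " km\n", sep = "")
  }
  cat("Distance-decay model selection (", x$family, " family):\n", sep = "")
  for (resp in names(x$decay)) {
    for (ct in names(x$decay[[resp]]$best))
      cat("  ", resp, " / ", ct, ": best = ",
          x$decay[[resp]]$best[[ct]], "\n", sep = "")
  }
  invisible(x)
}
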