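#' Synthetic scenario configuration
#'
#' Defines the study conditions emulated by the generator: a patchy
#' multi-class 10-m land-cover raster (~10 x 10 km), two spatially
#' separated countries of road-side sites at least 1 km apart, plant
#' communities structuring site quality, and bee communities whose
#' between-site similarity decays with corridor (or Euclidean) distance,
#' faster for solitary bees than for bumblebees.
#'
#' @param seed Integer RNG seed.
#' @param dim Fine raster dimensions `c(nrow, ncol)` at `cell_size`.
#' @param cell_size Fine cell size in metres.
#' @param smoothing Box-filter radius (cells) of the latent patch field;
#'   larger values give larger, sparser patches.
#' @param weights Land-cover mixture weights (must sum to 1) for
#'   sealed, cropland, sparse, herbaceous, low_woody, forest.
#' @param n_sites Sites per country, `c(west, east)`.
#' @param min_separation Minimum pairwise site distance (m).
#' @param n_bumblebee,n_solitary,n_parasitic,n_plants Species pool sizes.
#' @param n_cryptic Bumblebee species pooled as one cryptic morphospecies.
#' @param lambda_bumblebee,lambda_solitary,lambda_plant Distance-decay
#'   scales (km) of occupancy away from a species' home site; solitary
#'   bees disperse less than bumblebees, so
#'   `lambda_solitary < lambda_bumblebee`.
#' @param p0 Baseline occupancy probability at the home site.
#' @param quality_lls,quality_plants Effect (log-odds per SD) of local
#'   LLS length and plant richness on site quality.
#' @param truth `"corridor"` (occupancy decays with least-cost-path
#'   length along seminatural edges) or `"euclidean"` (decays with
#'   straight-line distance).
#' @param aggregation_factor Fine cells per conductance-surface cell.
#' @param eps Conductance floor.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            dim = c(1000L, 1000L),
                            cell_size = 10,
                            smoothing = 40L,
                            weights = c(sealed = 0.03, cropland = 0.54,
                                        sparse = 0.04, herbaceous = 0.10,
                                        low_woody = 0.05, forest = 0.24),
                            n_sites = c(20L, 20L),
                            min_separation = 1000,
                            n_bumblebee = 15L, n_solitary = 64L,
                            n_parasitic = 8L, n_plants = 40L,
                            n_cryptic = 4L,
                            lambda_bumblebee = 12, lambda_solitary = 5,
                            lambda_plant = 30,
                            p0 = 0.85,
                            quality_lls = 0, quality_plants = 0.5,
                            truth = c("corridor", "euclidean"),
                            aggregation_factor = 10L,
                            eps = 1e-6) {
  truth <- match.arg(truth)
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (lambda_bumblebee <= 0 || lambda_solitary <= 0)
    stop("decay scales must be > 0")
  if (min_separation < 0) stop("min_separation must be >= 0")
  structure(as.list(environment()), class = "scenario_config")
}

# separable box smoothing by integral image; reflects nothing, normalizes
# by the true window size so edges are unbiased
box_smooth <- function(m, r) {
  if (r < 1L) return(m)
  csum <- function(a, k) {
    n <- nrow(a)
    cs <- rbind(0, apply(a, 2, cumsum))
    hi <- pmin(seq_len(n) + k, n) + 1L
    lo <- pmax(seq_len(n) - k - 1L, 0L) + 1L
    (cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (pmin(seq_len(n) + k, n) - pmax(seq_len(n) - k, 1L) + 1L)
  }
  t(csum(t(csum(m, r)), r))
}

#' Simulate a patchy land-cover raster
#'
#' Thresholds a box-smoothed Gaussian random field into the land-cover
#' classes at the configured mixture weights, so each class forms
#' contiguous patches and boundaries form connected linear structures.
#' Forest cells are split between needle-leaved (2) and broadleaved (3)
#' by a second smoothed field.
#'
#' @param cfg A `scenario_config`. Uses the current RNG state; seed via
#'   [generate_scenario()] for reproducible bundles.
#' @return A `land_cover_grid`.
#' @export
simulate_landscape <- function(cfg) {
  nr <- cfg$dim[1]; ncg <- cfg$dim[2]
  z <- box_smooth(matrix(stats::rnorm(nr * ncg), nr, ncg), cfg$smoothing)
  codes <- c(sealed = 1L, cropland = 7L, sparse = 9L, herbaceous = 6L,
             low_woody = 5L, forest = 2L)
  w <- cfg$weights[names(codes)]
  br <- stats::quantile(z, cumsum(w) / sum(w), names = FALSE)
  cls <- codes[pmin(findInterval(z, br[-length(br)], left.open = TRUE) + 1L,
                    length(codes))]
  v <- matrix(cls, nr, ncg)
  if (any(v == 2L)) {
    z2 <- box_smooth(matrix(stats::rnorm(nr * ncg), nr, ncg),
                     max(cfg$smoothing %/% 2L, 1L))
    v[v == 2L & z2 > 0] <- 3L
  }
  land_cover_grid(v, cfg$cell_size, origin = c(0, 0))
}

#' Simulate site locations
#'
#' Rejection-samples site coordinates with all pairwise distances at
#' least `min_separation`, splits countries spatially (west / east
#' half), and draws a provisional plant richness from a site-quality
#' latent (replaced by realized plant richness once plant communities
#' are simulated).
#'
#' @param cfg A `scenario_config`.
#' @param grid The `land_cover_grid` sites are placed on.
#' @return A `site_table` with a `quality` latent attribute.
#' @export
simulate_sites <- function(cfg, grid) {
  ext <- c(ncol(grid$values), nrow(grid$values)) * grid$cell_size
  margin <- max(2 * grid$cell_size, 0.02 * min(ext))
  n_w <- cfg$n_sites[1]; n_e <- cfg$n_sites[2]
  n <- n_w + n_e
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > 1e5)
      stop("could not place ", n, " sites at ", cfg$min_separation,
           " m separation; reduce n_sites or separation")
    west <- length(xs) < n_w
    x <- stats::runif(1, if (west) margin else ext[1] / 2,
                      if (west) ext[1] / 2 else ext[1] - margin)
    y <- stats::runif(1, margin, ext[2] - margin)
    if (length(xs) &&
        min(sqrt((xs - x)^2 + (ys - y)^2)) < cfg$min_separation) next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  country <- rep(c("west", "east"), c(n_w, n_e))
  qlat <- stats::rnorm(n)
  plant_sr <- stats::rpois(n, exp(log(12) + 0.3 * qlat))
  st <- site_table(sprintf("S%02d", seq_len(n)), xs, ys, country, plant_sr)
  attr(st, "quality") <- qlat
  st
}

#' Simulate bee and plant communities
#'
#' Every species receives a random home site; its occupancy probability
#' at site j is `p0 * exp(-D(home, j) / lambda_group) * quality(j)`,
#' Bernoulli-thinned, where D is the least-cost-path length along
#' seminatural edges (corridor truth) or the Euclidean distance
#' (euclidean truth). Site quality combines local LLS length (1000-m
#' radius) and plant richness on the logistic scale. Occupied cells
#' receive `rpois(1) + 1` individuals. Kleptoparasites are generated
#' with host-tracking (distance-free) sparse occupancy and flagged; a
#' cryptic complex is embedded among the bumblebees.
#'
#' @param cfg A `scenario_config`.
#' @param sites `site_table` from [simulate_sites()].
#' @param grid `land_cover_grid` from [simulate_landscape()].
#' @return List: `occ_bees`, `occ_plants`, `traits`, `truth` (true
#'   parameters and the distance matrices used), and `sites` with
#'   realized plant richness.
#' @export
simulate_communities <- function(cfg, sites, grid) {
  n <- nrow(sites)
  lls <- extract_boundaries(grid, seminatural_class_sets())
  prop <- aggregate_proportion(rasterize_lines(lls, grid),
                               cfg$aggregation_factor)
  xy <- cbind(sites$x, sites$y)
  cells <- cell_of(prop, xy, labels = sites$id)
  ncg <- ncol(prop$values)
  ids <- (cells[, 1] - 1L) * ncg + cells[, 2]
  D_corr <- matrix(0, n, n)
  for (s in seq_len(n)) {
    res <- dijkstra_grid(prop$values, cfg$eps, ids[s], ids)
    D_corr[s, ] <- vapply(res$paths, function(p)
      path_from_ids(p, 0, prop)$length_m, numeric(1)) / 1000
  }
  D_euc <- as.matrix(stats::dist(xy)) / 1000
  D <- if (cfg$truth == "corridor") D_corr else D_euc

  lls_1km <- vapply(seq_len(n), function(i)
    length_within_radius(lls, xy[i, ], 1000), numeric(1))
  qlat <- attr(sites, "quality")
  if (is.null(qlat)) qlat <- stats::rnorm(n)

  # plants first: Euclidean decay; realized richness feeds site quality
  p_occ <- function(Dm, home, lambda, q)
    pmin(cfg$p0 * exp(-Dm[home, ] / lambda) * q, 1)
  q_plant <- stats::plogis(1.2 + 0.6 * qlat)
  occ_plants <- matrix(0L, n, cfg$n_plants,
                       dimnames = list(sites$id,
                                       sprintf("Plant_%02d",
                                               seq_len(cfg$n_plants))))
  for (sp in seq_len(cfg$n_plants)) {
    home <- sample.int(n, 1)
    occ <- stats::rbinom(n, 1, p_occ(D_euc, home, cfg$lambda_plant, q_plant))
    occ[home] <- 1L
    occ_plants[, sp] <- occ * (stats::rpois(n, 1) + 1L)
  }
  plant_sr <- as.integer(rowSums(occ_plants > 0))
  sites$plant_richness <- plant_sr

  zs <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  quality <- stats::plogis(0.8 + cfg$quality_lls * zs(log(lls_1km + 1)) +
                             cfg$quality_plants * zs(plant_sr))

  n_bee <- cfg$n_bumblebee + cfg$n_solitary + cfg$n_parasitic
  bee_names <- c(sprintf("Bombus_%02d", seq_len(cfg$n_bumblebee)),
                 sprintf("Solitary_%02d", seq_len(cfg$n_solitary)),
                 sprintf("Klepto_%02d", seq_len(cfg$n_parasitic)))
  group <- rep(c("bumblebee", "solitary", "solitary"),
               c(cfg$n_bumblebee, cfg$n_solitary, cfg$n_parasitic))
  parasitic <- rep(c(FALSE, FALSE, TRUE),
                   c(cfg$n_bumblebee, cfg$n_solitary, cfg$n_parasitic))
  cryptic <- rep(NA_character_, n_bee)
  if (cfg$n_cryptic > 0 && cfg$n_bumblebee >= cfg$n_cryptic)
    cryptic[seq_len(cfg$n_cryptic)] <- "Bombus_sstr"
  traits <- species_traits(bee_names, parasitic, group, cryptic)

  occ_bees <- matrix(0L, n, n_bee, dimnames = list(sites$id, bee_names))
  for (sp in seq_len(n_bee)) {
    home <- sample.int(n, 1)
    if (parasitic[sp]) {
      occ <- stats::rbinom(n, 1, 0.08)           # tracks hosts, not habitat
    } else {
      lam <- if (group[sp] == "bumblebee") cfg$lambda_bumblebee
             else cfg$lambda_solitary
      occ <- stats::rbinom(n, 1, p_occ(D, home, lam, quality))
    }
    occ_bees[, sp] <- occ * (stats::rpois(n, 1) + 1L)
  }
  list(occ_bees = occurrence_table(occ_bees),
       occ_plants = occurrence_table(occ_plants),
       traits = traits, sites = sites,
       truth = list(mode = cfg$truth,
                    lambda_bumblebee = cfg$lambda_bumblebee,
                    lambda_solitary = cfg$lambda_solitary,
                    p0 = cfg$p0, quality = quality,
                    lcp_km = D_corr, euclid_km = D_euc,
                    edge_grid = prop))
}

#' Generate a complete synthetic scenario
#'
#' Seeds the RNG and composes [simulate_landscape()],
#' [simulate_sites()] and [simulate_communities()] into a bundle; the
#' same seed always yields a bit-identical bundle. Optionally writes all
#' components as plain-text files (ASCII grid, CSVs, truth JSON).
#'
#' @param cfg A `scenario_config`.
#' @param dir Optional output directory.
#' @return List of class `scenario_bundle`: `cfg`, `grid`, `sites`,
#'   `occ_bees`, `occ_plants`, `traits`, `truth`.
#' @export
generate_scenario <- function(cfg = scenario_config(), dir = NULL) {
  set.seed(cfg$seed)
  grid <- simulate_landscape(cfg)
  sites <- simulate_sites(cfg, grid)
  com <- simulate_communities(cfg, sites, grid)
  bundle <- structure(list(cfg = cfg, grid = grid, sites = com$sites,
                           occ_bees = com$occ_bees,
                           occ_plants = com$occ_plants,
                           traits = com$traits, truth = com$truth),
                      class = "scenario_bundle")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_ascii_grid(grid, file.path(dir, "landcover.asc"))
    utils::write.csv(as.data.frame(bundle$sites),
                     file.path(dir, "sites.csv"), row.names = FALSE)
    write_occurrences_csv(bundle$occ_bees, file.path(dir, "bees.csv"))
    write_occurrences_csv(bundle$occ_plants, file.path(dir, "plants.csv"))
    utils::write.csv(bundle$traits, file.path(dir, "traits.csv"),
                     row.names = FALSE)
    tr <- bundle$truth
    tr$quality <- as.numeric(tr$quality)
    tr$lcp_km <- NULL; tr$euclid_km <- NULL; tr$edge_grid <- NULL
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat("<scenario_bundle> seed ", x$cfg$seed, ", truth ", x$truth$mode, "\n",
      sep = "")
  cat("  raster ", nrow(x$grid$values), "x", ncol(x$grid$values), " @ ",
      x$grid$cell_size, " m; ", nrow(x$sites), " sites (",
      paste(table(x$sites$country), collapse = " + "), ")\n", sep = "")
  cat("  bees: ", ncol(x$occ_bees), " species, ",
      sum(unclass(x$occ_bees) > 0), " occurrences; plants: ",
      ncol(x$occ_plants), " species\n", sep = "")
  invisible(x)
}

write_occurrences_csv <- function(occ, path) {
  m <- unclass(occ)
  idx <- which(m > 0, arr.ind = TRUE)
  long <- data.frame(site = rownames(m)[idx[, 1]],
                     species = colnames(m)[idx[, 2]],
                     count = m[idx])
  long <- long[order(long$site, long$species), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
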