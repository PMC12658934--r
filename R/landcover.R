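#' Extract patch boundaries as linear landscape structures
#'
#' Polygonizes each class set separately and traces the boundary faces
#' between cells inside and outside the set, emitting one unit segment
#' (one cell edge) per face. Faces on the raster border or adjacent to
#' nodata cells are excluded, and exact-duplicate faces arising from two
#' adjacent class sets (e.g. a forest-grassland face) are counted once.
#'
#' @param grid A `land_cover_grid`.
#' @param class_sets A list of integer class-code vectors (or a single
#'   vector), each polygonized separately; e.g. [seminatural_class_sets()].
#' @param class_tag Tag stored on the returned `line_set`.
#' @return A `line_set` of boundary segments.
#' @export
extract_boundaries <- function(grid, class_sets,
                               class_tag = "all_seminatural") {
  if (!inherits(grid, "land_cover_grid")) stop("grid must be a land_cover_grid")
  if (!is.list(class_sets)) class_sets <- list(class_sets)
  if (length(class_sets) == 0L) stop("class_sets must be nonempty")
  codes <- landcover_codes()
  for (cs in class_sets)
    if (length(setdiff(cs, codes)))
      stop("unknown class codes: ",
           paste(setdiff(cs, codes), collapse = ", "))
  v <- grid$values
  valid <- !is.na(v)
  if (!is.na(grid$nodata)) valid <- valid & v != grid$nodata
  nr <- nrow(v); ncg <- ncol(v); cs <- grid$cell_size
  x0 <- grid$origin[1]; y0 <- grid$origin[2]

  vert <- matrix(FALSE, nr, max(ncg - 1L, 0L))   # face (r,c)-(r,c+1)
  horz <- matrix(FALSE, max(nr - 1L, 0L), ncg)   # face (r,c)-(r+1,c)
  for (set in class_sets) {
    m <- matrix(v %in% set, nr, ncg)
    if (ncg > 1L) {
      f <- (m[, -ncg, drop = FALSE] != m[, -1L, drop = FALSE]) &
        valid[, -ncg, drop = FALSE] & valid[, -1L, drop = FALSE]
      vert <- vert | f
    }
    if (nr > 1L) {
      f <- (m[-nr, , drop = FALSE] != m[-1L, , drop = FALSE]) &
        valid[-nr, , drop = FALSE] & valid[-1L, , drop = FALSE]
      horz <- horz | f
    }
  }
  segs <- matrix(numeric(0), ncol = 4)
  if (any(vert)) {
    idx <- which(vert, arr.ind = TRUE)           # left cell (r, c)
    x <- x0 + idx[, 2] * cs                      # shared vertical edge
    segs <- rbind(segs, cbind(x, y0 + (idx[, 1] - 1) * cs,
                              x, y0 + idx[, 1] * cs))
  }
  if (any(horz)) {
    idx <- which(horz, arr.ind = TRUE)           # lower cell (r, c)
    y <- y0 + idx[, 1] * cs                      # shared horizontal edge
    segs <- rbind(segs, cbind(x0 + (idx[, 2] - 1) * cs, y,
                              x0 + idx[, 2] * cs, y))
  }
  line_set(segs, class_tag)
}

#' Length of nonforest seminatural structures
#'
#' The length of all seminatural LLS minus the length of forest edges,
#' floored at zero.
#'
#' @param all_lls `line_set` of all seminatural boundaries.
#' @param forest `line_set` of forest-edge boundaries.
#' @return Length in metres.
#' @export
nonforest_length <- function(all_lls, forest) {
  max(total_length(all_lls) - total_length(forest), 0)
}

#' Aggregate a binary grid to proportions
#'
#' Each coarse cell holds the fraction of fine 1-cells in its
#' `factor` x `factor` block. Grids whose dimensions are not divisible by
#' `factor` are zero-padded on the north/east side, so the count of
#' 1-cells is conserved exactly.
#'
#' @param fine A `binary_grid`.
#' @param factor Fine cells per coarse cell per axis (>= 1).
#' @return A `proportion_grid`.
#' @export
aggregate_proportion <- function(fine, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  v <- fine$values
  nr <- nrow(v); ncg <- ncol(v)
  NR <- ceiling(nr / factor); NC <- ceiling(ncg / factor)
  if (NR * factor > nr || NC * factor > ncg) {
    pad <- matrix(0L, NR * factor, NC * factor)
    pad[seq_len(nr), seq_len(ncg)] <- v
    v <- pad
  }
  rg <- (seq_len(NR * factor) - 1L) %/% factor + 1L
  cg <- (seq_len(NC * factor) - 1L) %/% factor + 1L
  sums <- rowsum(t(rowsum(v, rg)), cg)           # NC x NR block sums
  proportion_grid(t(sums) / factor^2, fine$cell_size * factor,
                  fine$origin, factor)
}

#' Grassland proportion within a radius
#'
#' Fraction of cells whose centres fall in the closed disc around a point
#' that carry the grassland (permanent herbaceous) class code.
#'
#' @param grid A `land_cover_grid`.
#' @param center `(x, y)` in metres.
#' @param radius Radius in metres (> 0).
#' @param grass_code Class code counted as grassland (default 6).
#' @return Fraction in \[0, 1\].
#' @export
grassland_proportion <- function(grid, center, radius, grass_code = 6L) {
  if (radius <= 0) stop("radius must be > 0")
  v <- grid$values
  cs <- grid$cell_size
  xc <- grid$origin[1] + (seq_len(ncol(v)) - 0.5) * cs
  yc <- grid$origin[2] + (seq_len(nrow(v)) - 0.5) * cs
  dx2 <- (xc - center[1])^2
  dy2 <- (yc - center[2])^2
  inside <- outer(dy2, dx2, "+") <= radius^2
  n <- sum(inside)
  if (n == 0L) stop("no cell centers inside the disc")
  sum(v[inside] == grass_code, na.rm = TRUE) / n
}

#' Per-site landscape metrics across radii
#'
#' For every site and radius, the length of each LLS type within the
#' radius (metres) and the grassland proportion, i.e. the landscape
#' covariates of the richness models.
#'
#' @param sites A site table (see [site_table()]).
#' @param lls `line_set` of all seminatural boundaries.
#' @param forest `line_set` of forest-edge boundaries.
#' @param grid The `land_cover_grid` (for grassland proportions).
#' @param radii Radii in metres (default 250–1500 m by 250 m).
#' @return Data frame: site, radius, lls_all_m, lls_forest_m,
#'   lls_nonforest_m, grassland_prop.
#' @export
site_landscape_metrics <- function(sites, lls, forest, grid,
                                   radii = c(250, 500, 750, 1000, 1250, 1500)) {
  out <- expand.grid(site = sites$id, radius = radii,
                     stringsAsFactors = FALSE)
  out$lls_all_m <- NA_real_; out$lls_forest_m <- NA_real_
  out$grassland_prop <- NA_real_
  for (k in seq_len(nrow(out))) {
    i <- match(out$site[k], sites$id)
    ctr <- c(sites$x[i], sites$y[i])
    out$lls_all_m[k] <- length_within_radius(lls, ctr, out$radius[k])
    out$lls_forest_m[k] <- length_within_radius(forest, ctr, out$radius[k])
    out$grassland_prop[k] <- grassland_proportion(grid, ctr, out$radius[k])
  }
  out$lls_nonforest_m <- pmax(out$lls_all_m - out$lls_forest_m, 0)
  out
}
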