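#' Site table
#'
#' @param id Unique site identifiers.
#' @param x,y Projected coordinates in metres.
#' @param country Country label per site.
#' @param plant_richness Flowering plant species richness per site.
#' @return A data frame of class `site_table`.
#' @export
site_table <- function(id, x, y, country, plant_richness = NA_integer_) {
  if (anyDuplicated(id)) stop("site ids must be unique")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("site coordinates must be finite")
  if (any(!is.na(plant_richness) & plant_richness < 0))
    stop("plant_richness must be >= 0")
  out <- data.frame(id = as.character(id), x = as.numeric(x),
                    y = as.numeric(y), country = as.character(country),
                    plant_richness = plant_richness,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_table", "data.frame")
  out
}

#' Conductance graph over a proportion grid
#'
#' Implicit 8-neighbour graph on coarse cells. The conductance between
#' neighbouring cells i and j is `mean(x_i, x_j) / d_ij` with
#' `d_ij` in cell units (1 for rook, sqrt(2) for diagonal moves) and cell
#' proportions floored at `eps`; the edge cost (the travelled weight) is
#' its reciprocal `1/x`, so costs grow steeply as the proportion of
#' linear structures falls, and the floor keeps the graph connected.
#'
#' @param grid A `proportion_grid`.
#' @param eps Conductance floor replacing zero proportions (default 1e-6).
#' @return An object of class `conductance_graph`.
#' @export
conductance_graph <- function(grid, eps = 1e-6) {
  if (!inherits(grid, "proportion_grid")) stop("grid must be a proportion_grid")
  if (!(eps > 0 && eps < 1)) stop("eps must be in (0, 1)")
  structure(list(grid = grid, eps = eps,
                 nrow = nrow(grid$values), ncol = ncol(grid$values)),
            class = "conductance_graph")
}

#' @export
print.conductance_graph <- function(x, ...) {
  cat("<conductance_graph> ", x$nrow, "x", x$ncol,
      " cells, 8-neighbour, eps = ", x$eps, "\n", sep = "")
  invisible(x)
}

#' Materialized edge list of a conductance graph
#'
#' Mainly for inspection and testing; path computations use the implicit
#' graph directly.
#'
#' @param graph A `conductance_graph`.
#' @return Data frame with 0-based-free 1-based row-major node ids `from`,
#'   `to` (`from < to`) and the symmetric edge `weight` (cost).
#' @export
graph_edges <- function(graph) {
  v <- pmax(graph$grid$values, graph$eps)
  nr <- graph$nrow; ncg <- graph$ncol
  id <- function(r, c) (r - 1L) * ncg + c
  from <- integer(0); to <- integer(0); w <- numeric(0)
  steps <- list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)),
                c(1L, -1L, sqrt(2)))
  for (s in steps) {
    rr <- seq_len(nr - s[1]); cc <- seq_len(ncg)
    cc <- cc[cc + s[2] >= 1 & cc + s[2] <= ncg]
    if (!length(rr) || !length(cc)) next
    g <- expand.grid(r = rr, c = cc)
    a <- id(g$r, g$c); b <- id(g$r + s[1], g$c + s[2])
    from <- c(from, pmin(a, b)); to <- c(to, pmax(a, b))
    w <- c(w, s[3] / (0.5 * (v[cbind(g$r, g$c)] +
                             v[cbind(g$r + s[1], g$c + s[2])])))
  }
  o <- order(from, to)
  data.frame(from = from[o], to = to[o], weight = w[o])
}

#' Least-cost path between two cells
#'
#' Dijkstra's algorithm on the implicit conductance graph, with
#' deterministic tie-breaking (equal-cost routes keep the predecessor
#' with the lowest row-major index).
#'
#' @param graph A `conductance_graph`.
#' @param src,dst Cells as `c(row, col)`.
#' @return An object of class `corridor_path` with elements `cells`
#'   (ordered m x 2 matrix), `length_m` (polyline length through cell
#'   centres), `cost` (sum of `1 - x` over path cells), and `graph_cost`
#'   (accumulated edge weights, cell units).
#' @export
least_cost_path <- function(graph, src, dst) {
  ncg <- graph$ncol
  sid <- (src[1] - 1L) * ncg + src[2]
  did <- (dst[1] - 1L) * ncg + dst[2]
  if (src[1] < 1 || src[1] > graph$nrow || src[2] < 1 || src[2] > ncg)
    stop("src out of bounds")
  if (dst[1] < 1 || dst[1] > graph$nrow || dst[2] < 1 || dst[2] > ncg)
    stop("dst out of bounds")
  res <- dijkstra_grid(graph$grid$values, graph$eps, sid, did)
  path_from_ids(res$paths[[1]], res$dist[1], graph$grid)
}

path_from_ids <- function(ids, graph_cost, grid) {
  ncg <- ncol(grid$values)
  cells <- cbind(row = (ids - 1L) %/% ncg + 1L,
                 col = (ids - 1L) %% ncg + 1L)
  len <- 0
  if (nrow(cells) > 1L) {
    dr <- abs(diff(cells[, 1])); dc <- abs(diff(cells[, 2]))
    len <- sum(ifelse(dr + dc == 2L, sqrt(2), 1)) * grid$cell_size
  }
  structure(list(cells = cells, length_m = len,
                 cost = sum(1 - grid$values[cells]),
                 graph_cost = graph_cost),
            class = "corridor_path")
}

#' @export
print.corridor_path <- function(x, ...) {
  cat("<corridor_path> ", nrow(x$cells), " cells, length ",
      round(x$length_m / 1000, 3), " km, cost ", round(x$cost, 3),
      ", graph cost ", round(x$graph_cost, 3), "\n", sep = "")
  invisible(x)
}

#' Corridor metrics of a path
#'
#' @param path A `corridor_path`.
#' @param grid The `proportion_grid` the path was computed on.
#' @return List with `length_km` (centre-to-centre polyline length) and
#'   `cost` (sum of `1 - x` over path cells, endpoints included, each
#'   visited cell counted once).
#' @export
corridor_metrics <- function(path, grid) {
  cells <- path$cells
  len <- 0
  if (nrow(cells) > 1L) {
    dr <- abs(diff(cells[, 1])); dc <- abs(diff(cells[, 2]))
    len <- sum(ifelse(dr + dc == 2L, sqrt(2), 1)) * grid$cell_size
  }
  list(length_km = len / 1000, cost = sum(1 - grid$values[cells]))
}

#' Euclidean geographic distance in kilometres
#'
#' @param p1,p2 Points `(x, y)` in projected metres, or two-column
#'   matrices of points.
#' @return Distance(s) in km.
#' @export
geographic_distance <- function(p1, p2) {
  p1 <- matrix(as.numeric(p1), ncol = 2)
  p2 <- matrix(as.numeric(p2), ncol = 2)
  sqrt((p1[, 1] - p2[, 1])^2 + (p1[, 2] - p2[, 2])^2) / 1000
}

#' Pairwise distances between same-country sites
#'
#' For every unordered within-country site pair, the geographic distance
#' and, per supplied proportion grid, the least-cost-path length and
#' accumulated cost. Sites are snapped to their containing coarse cell,
#' so path lengths are centre-to-centre with at most one-cell
#' discretization error.
#'
#' @param sites A `site_table`.
#' @param grids Named list of `proportion_grid`s (e.g.
#'   `list(lls = ..., forest = ...)`).
#' @param eps Conductance floor passed to [conductance_graph()].
#' @return Data frame with columns site_i, site_j, country, geo_km and,
#'   per grid name, `lcp_len_<name>_km` and `lcp_cost_<name>`.
#' @export
pairwise_distances <- function(sites, grids, eps = 1e-6) {
  stopifnot(length(grids) >= 1, !is.null(names(grids)))
  pairs <- within_country_pairs(sites)
  if (nrow(pairs) == 0L) stop("need at least 2 sites in some country")
  xy <- cbind(sites$x, sites$y)
  ii <- match(pairs$site_i, sites$id); jj <- match(pairs$site_j, sites$id)
  pairs$geo_km <- geographic_distance(xy[ii, , drop = FALSE],
                                      xy[jj, , drop = FALSE])
  for (nm in names(grids)) {
    grid <- grids[[nm]]
    cells <- cell_of(grid, xy, labels = sites$id)
    ncg <- ncol(grid$values)
    ids <- (cells[, 1] - 1L) * ncg + cells[, 2]
    lens <- costs <- numeric(nrow(pairs))
    for (s in unique(ii)) {
      rows <- which(ii == s)
      res <- dijkstra_grid(grid$values, eps, ids[s], ids[jj[rows]])
      for (k in seq_along(rows)) {
        p <- path_from_ids(res$paths[[k]], res$dist[k], grid)
        lens[rows[k]] <- p$length_m / 1000
        costs[rows[k]] <- p$cost
      }
    }
    pairs[[paste0("lcp_len_", nm, "_km")]] <- lens
    pairs[[paste0("lcp_cost_", nm)]] <- costs
  }
  pairs
}

within_country_pairs <- function(sites) {
  out <- list()
  for (ct in unique(sites$country)) {
    ids <- sites$id[sites$country == ct]
    if (length(ids) < 2L) next
    cmb <- utils::combn(ids, 2)
    out[[ct]] <- data.frame(site_i = cmb[1, ], site_j = cmb[2, ],
                            country = ct, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(site_i = character(0), site_j = character(0),
                      country = character(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}
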