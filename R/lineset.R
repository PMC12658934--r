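#' Line set
#'
#' A set of line segments in projected metric coordinates. Polyline input is
#' decomposed into its constituent two-vertex segments; internally a line
#' set is an n x 4 matrix with columns `x1, y1, x2, y2`.
#'
#' @param segments Either an n x 4 numeric matrix (`x1, y1, x2, y2`) or a
#'   list of polylines, each an m x 2 vertex matrix with m >= 2.
#' @param class_tag Which class set produced the lines
#'   (`"all_seminatural"`, `"forest"`, `"nonforest"`, ...).
#' @return An object of class `line_set`.
#' @export
line_set <- function(segments, class_tag = "all_seminatural") {
  if (is.list(segments) && !is.matrix(segments)) {
    segs <- lapply(segments, function(p) {
      p <- as.matrix(p)
      if (nrow(p) < 2L) stop("every polyline needs at least 2 vertices")
      cbind(p[-nrow(p), 1], p[-nrow(p), 2], p[-1, 1], p[-1, 2])
    })
    segments <- do.call(rbind, segs)
  }
  if (is.null(segments) || length(segments) == 0L)
    segments <- matrix(numeric(0), ncol = 4)
  segments <- matrix(as.numeric(segments), ncol = 4)
  colnames(segments) <- c("x1", "y1", "x2", "y2")
  structure(list(segments = segments, class_tag = class_tag),
            class = "line_set")
}

#' Total length of a line set
#' @param lines A `line_set`.
#' @return Total segment length in metres.
#' @export
total_length <- function(lines) {
  s <- lines$segments
  if (nrow(s) == 0L) return(0)
  sum(sqrt((s[, 3] - s[, 1])^2 + (s[, 4] - s[, 2])^2))
}

#' @export
print.line_set <- function(x, ...) {
  cat("<line_set> ", nrow(x$segments), " segments (", x$class_tag, "), ",
      "total length ", round(total_length(x), 1), " m\n", sep = "")
  invisible(x)
}

#' Length of line features within a radius
#'
#' Clips every segment to the closed disc of the given radius around a
#' centre point and sums the clipped lengths (exact closed-form
#' segment-circle intersection).
#'
#' @param lines A `line_set`.
#' @param center Numeric length-2, `(x, y)` in metres.
#' @param radius Radius in metres (>= 0).
#' @return Clipped total length in metres.
#' @export
length_within_radius <- function(lines, center, radius) {
  if (radius < 0) stop("radius must be >= 0")
  s <- lines$segments
  if (nrow(s) == 0L || radius == 0) return(0)
  dx <- s[, 3] - s[, 1]; dy <- s[, 4] - s[, 2]
  fx <- s[, 1] - center[1]; fy <- s[, 2] - center[2]
  a <- dx^2 + dy^2
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx^2 + fy^2 - radius^2
  len <- sqrt(a)
  out <- numeric(nrow(s))
  pt <- a == 0                                  # degenerate zero-length
  disc <- b^2 - 4 * a * cc
  no <- !pt & disc <= 0                         # no chord: all in or all out
  out[no] <- ifelse(cc[no] <= 0, len[no], 0)
  ok <- !pt & disc > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- pmax((-b[ok] - sq) / (2 * a[ok]), 0)
    t2 <- pmin((-b[ok] + sq) / (2 * a[ok]), 1)
    out[ok] <- pmax(t2 - t1, 0) * len[ok]
  }
  sum(out)
}

#' Rasterize line features onto a grid
#'
#' A cell is marked 1 when any segment intersects the cell's *closed*
#' square; a segment lying exactly on the shared edge of two cells
#' therefore marks both, and a segment endpoint on a cell corner marks
#' every cell meeting at that corner. This closed-cell rule is
#' deterministic and orientation-free.
#'
#' @param lines A `line_set`.
#' @param template A grid object supplying extent, origin and cell size, or
#'   `NULL` to pass `cell_size`, `dim` and `origin` directly.
#' @param cell_size,dim,origin Grid geometry when `template` is `NULL`;
#'   `dim` is `c(nrow, ncol)`.
#' @return A `binary_grid` on the template geometry.
#' @export
rasterize_lines <- function(lines, template = NULL, cell_size = NULL,
                            dim = NULL, origin = c(0, 0)) {
  if (!is.null(template)) {
    cell_size <- template$cell_size
    dim <- base::dim(template$values)
    origin <- template$origin
  }
  if (is.null(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  nr <- dim[1]; ncg <- dim[2]
  m <- matrix(0L, nr, ncg)
  s <- lines$segments
  if (nrow(s) > 0L) {
    # grid-unit coordinates: cell c spans [c-1, c], row r spans [r-1, r]
    u1 <- (s[, 1] - origin[1]) / cell_size
    v1 <- (s[, 2] - origin[2]) / cell_size
    u2 <- (s[, 3] - origin[1]) / cell_size
    v2 <- (s[, 4] - origin[2]) / cell_size
    axis <- u1 == u2 | v1 == v2
    if (any(axis)) {
      # axis-aligned: closed bounding-box overlap IS intersection
      umin <- pmin(u1, u2)[axis]; umax <- pmax(u1, u2)[axis]
      vmin <- pmin(v1, v2)[axis]; vmax <- pmax(v1, v2)[axis]
      cl <- pmax(1L, ceiling(umin)); ch <- pmin(ncg, floor(umax) + 1L)
      rl <- pmax(1L, ceiling(vmin)); rh <- pmin(nr, floor(vmax) + 1L)
      keep <- cl <= ch & rl <= rh
      cl <- cl[keep]; ch <- ch[keep]; rl <- rl[keep]; rh <- rh[keep]
      if (length(cl)) {
        nrow_i <- rh - rl + 1L
        sid <- rep.int(seq_along(rl), nrow_i)
        rr <- sequence(nrow_i) + rep.int(rl, nrow_i) - 1L
        ncol_i <- (ch - cl + 1L)[sid]
        rr2 <- rep.int(rr, ncol_i)
        cc2 <- sequence(ncol_i) + rep.int(cl[sid], ncol_i) - 1L
        m[cbind(rr2, cc2)] <- 1L
      }
    }
    gen <- which(!axis)
    for (i in gen) {            # general segments: per-cell clip test
      cl <- max(1L, ceiling(min(u1[i], u2[i])))
      ch <- min(ncg, floor(max(u1[i], u2[i])) + 1L)
      rl <- max(1L, ceiling(min(v1[i], v2[i])))
      rh <- min(nr, floor(max(v1[i], v2[i])) + 1L)
      if (cl > ch || rl > rh) next
      for (r in rl:rh) for (cc in cl:ch) {
        if (segment_in_box(u1[i], v1[i], u2[i], v2[i],
                           cc - 1, cc, r - 1, r)) m[r, cc] <- 1L
      }
    }
  }
  binary_grid(m, cell_size, origin)
}

# closed-box Liang-Barsky style clip test in grid units
segment_in_box <- function(x1, y1, x2, y2, xlo, xhi, ylo, yhi) {
  dx <- x2 - x1; dy <- y2 - y1
  t0 <- 0; t1 <- 1
  for (side in 1:4) {
    p <- switch(side, -dx, dx, -dy, dy)
    q <- switch(side, x1 - xlo, xhi - x1, y1 - ylo, yhi - y1)
    if (p == 0) { if (q < 0) return(FALSE) } else {
      r <- q / p
      if (p < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

#' Export a line set as GeoJSON
#'
#' Each segment becomes a `LineString` feature carrying the `class_tag`
#' property.
#'
#' @param lines A `line_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lines_geojson <- function(lines, path) {
  s <- lines$segments
  feats <- lapply(seq_len(nrow(s)), function(i) {
    list(type = "Feature",
         properties = list(class_tag = lines$class_tag),
         geometry = list(type = "LineString",
                         coordinates = list(c(s[i, 1], s[i, 2]),
                                            c(s[i, 3], s[i, 4]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a line set as WKT
#'
#' One `LINESTRING` per segment, one per line of text.
#'
#' @param lines A `line_set`.
#' @param path Output file path, or `NULL` to return the strings.
#' @return Character vector of WKT strings (invisibly when written).
#' @export
write_lines_wkt <- function(lines, path = NULL) {
  s <- lines$segments
  wkt <- sprintf("LINESTRING (%g %g, %g %g)", s[, 1], s[, 2], s[, 3], s[, 4])
  if (is.null(path)) return(wkt)
  writeLines(wkt, path)
  invisible(wkt)
}
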