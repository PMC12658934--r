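#' Land-cover class codes
#'
#' The 11-class coding convention used throughout the package for categorical
#' land-cover rasters: 1 sealed, 2 woody needle-leaved, 3 woody broadleaved
#' deciduous, 4 woody broadleaved evergreen, 5 low-growing woody, 6 permanent
#' herbaceous (grassland), 7 periodically herbaceous (cropland), 8 lichens and
#' mosses, 9 non- and sparsely vegetated, 10 water, 11 snow and ice.
#'
#' @return Named integer vector of the recognised class codes.
#' @export
landcover_codes <- function() {
  c(sealed = 1L, woody_needle = 2L, woody_broadleaf = 3L,
    woody_evergreen = 4L, low_woody = 5L, herbaceous = 6L,
    cropland = 7L, lichen_moss = 8L, sparse = 9L,
    water = 10L, snow_ice = 11L)
}

#' Class-code sets for boundary extraction
#'
#' The four class groups whose patch boundaries constitute seminatural linear
#' landscape structures (LLS): forest (codes 2 and 3), low-growing woody
#' plants (5), permanent herbaceous grassland (6), and non- and sparsely
#' vegetated areas (9).
#'
#' @return Named list of integer code vectors.
#' @export
seminatural_class_sets <- function() {
  list(forest = c(2L, 3L), low_woody = 5L, herbaceous = 6L, sparse = 9L)
}

## ---- grid constructors ----------------------------------------------------

#' Categorical land-cover grid
#'
#' A minimal in-memory raster: an integer matrix of class codes plus cell
#' size and origin in a projected metric CRS. Matrix row 1 is the
#' *southernmost* row, so the cell centre of `values[r, c]` lies at
#' `(x0 + (c - 0.5) * cell_size, y0 + (r - 0.5) * cell_size)`.
#'
#' @param values Integer matrix of class codes.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Numeric length-2, `(x0, y0)` of the lower-left corner.
#' @param nodata Integer code treated as missing (default `NA`).
#' @param codes Declared code set; values outside it (and not nodata) error.
#' @return An object of class `land_cover_grid`.
#' @export
land_cover_grid <- function(values, cell_size, origin = c(0, 0),
                            nodata = NA_integer_, codes = landcover_codes()) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (nrow(values) < 1L || ncol(values) < 1L) stop("empty grid")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  present <- unique(values[!is.na(values)])
  if (!is.na(nodata)) present <- setdiff(present, nodata)
  bad <- setdiff(present, codes)
  if (length(bad))
    stop("class codes outside the declared code set: ",
         paste(sort(bad), collapse = ", "))
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), nodata = nodata),
            class = "land_cover_grid")
}

#' Binary feature grid
#'
#' 0/1 raster marking cells touched by rasterized line features.
#'
#' @param values 0/1 matrix (row 1 = southernmost row).
#' @param cell_size Cell edge length in metres.
#' @param origin `(x0, y0)` lower-left corner.
#' @return An object of class `binary_grid`.
#' @export
binary_grid <- function(values, cell_size, origin = c(0, 0)) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1))) stop("values must be 0 or 1")
  storage.mode(values) <- "integer"
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "binary_grid")
}

#' Proportion grid
#'
#' Coarse raster whose cells hold the fraction of fine 0/1 cells equal to 1
#' in the corresponding block; the substrate for conductance surfaces.
#'
#' @param values Matrix with entries in \[0, 1\].
#' @param cell_size Coarse cell edge length in metres.
#' @param origin `(x0, y0)` lower-left corner.
#' @param factor Fine cells per coarse cell along each axis.
#' @return An object of class `proportion_grid`.
#' @export
proportion_grid <- function(values, cell_size, origin = c(0, 0), factor = 1L) {
  values <- as.matrix(values)
  if (any(values < 0 | values > 1)) stop("proportions must lie in [0, 1]")
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), factor = as.integer(factor)),
            class = "proportion_grid")
}

#' @export
print.land_cover_grid <- function(x, ...) {
  cat("<land_cover_grid> ", nrow(x$values), "x", ncol(x$values),
      " cells, ", x$cell_size, " m resolution\n", sep = "")
  tab <- table(x$values)
  cat("  classes:", paste0(names(tab), " (", as.integer(tab), ")",
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.binary_grid <- function(x, ...) {
  cat("<binary_grid> ", nrow(x$values), "x", ncol(x$values), " cells, ",
      x$cell_size, " m resolution, ", sum(x$values), " marked cells\n",
      sep = "")
  invisible(x)
}

#' @export
print.proportion_grid <- function(x, ...) {
  cat("<proportion_grid> ", nrow(x$values), "x", ncol(x$values), " cells, ",
      x$cell_size, " m resolution (aggregation factor ", x$factor, ")\n",
      "  mean proportion: ", signif(mean(x$values), 4), "\n", sep = "")
  invisible(x)
}

## ---- cell geometry helpers ------------------------------------------------

#' Cell centre coordinates
#' @param grid Any grid object of this package.
#' @param rc Two-column matrix (row, col) of cell indices.
#' @return Two-column matrix of (x, y) centre coordinates in metres.
#' @export
cell_centers <- function(grid, rc) {
  rc <- matrix(as.numeric(rc), ncol = 2)
  cbind(grid$origin[1] + (rc[, 2] - 0.5) * grid$cell_size,
        grid$origin[2] + (rc[, 1] - 0.5) * grid$cell_size)
}

#' Containing cell of a point
#'
#' Maps projected coordinates to the (row, col) of the containing cell.
#' Points on an interior cell boundary belong to the higher-index cell;
#' points outside the grid extent give an error naming the offending point.
#'
#' @param grid Any grid object of this package.
#' @param xy Two-column matrix of (x, y) coordinates, metres.
#' @param labels Optional names used in error messages.
#' @return Two-column integer matrix (row, col).
#' @export
cell_of <- function(grid, xy, labels = NULL) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  cs <- grid$cell_size
  cc <- floor((xy[, 1] - grid$origin[1]) / cs) + 1L
  rr <- floor((xy[, 2] - grid$origin[2]) / cs) + 1L
  nr <- nrow(grid$values); ncg <- ncol(grid$values)
  # points exactly on the top/right extent edge belong to the last cell
  cc[xy[, 1] == grid$origin[1] + ncg * cs] <- ncg
  rr[xy[, 2] == grid$origin[2] + nr * cs] <- nr
  out <- rr < 1L | rr > nr | cc < 1L | cc > ncg
  if (any(out)) {
    who <- if (!is.null(labels)) paste(labels[out], collapse = ", ")
           else paste(which(out), collapse = ", ")
    stop("point(s) outside the raster extent: ", who)
  }
  cbind(row = as.integer(rr), col = as.integer(cc))
}

## ---- ESRI ASCII grid I/O --------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @param type `"landcover"`, `"binary"` or `"proportion"`.
#' @param ... Passed to the corresponding constructor.
#' @return A grid object of the requested type.
#' @export
read_ascii_grid <- function(path, type = c("landcover", "binary", "proportion"),
                            ...) {
  type <- match.arg(type)
  lines <- readLines(path)
  hdr <- list(); i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  vals <- scan(text = body, quiet = TRUE)
  nr <- hdr$nrows; ncg <- hdr$ncols
  m <- matrix(vals, nrow = nr, ncol = ncg, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]           # file is north-to-south; flip
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA
  if (!is.na(nodata)) m[m == nodata] <- if (type == "landcover") nodata else 0
  origin <- c(hdr$xllcorner, hdr$yllcorner)
  switch(type,
    landcover = land_cover_grid(m, hdr$cellsize, origin,
                                nodata = as.integer(nodata), ...),
    binary = binary_grid(m, hdr$cellsize, origin),
    proportion = proportion_grid(m, hdr$cellsize, origin, ...))
}

#' Write an ESRI ASCII grid
#'
#' @param grid Any grid object of this package.
#' @param path Output file path.
#' @param nodata Nodata code written in the header.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999L) {
  v <- grid$values
  nr <- nrow(v)
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nr),
           paste("xllcorner", grid$origin[1]),
           paste("yllcorner", grid$origin[2]),
           paste("cellsize", grid$cell_size),
           paste("NODATA_value", nodata))
  vv <- v[nr:1, , drop = FALSE]          # write north-to-south
  vv[is.na(vv)] <- nodata
  body <- apply(vv, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
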