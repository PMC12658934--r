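# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (face scans, per-cell clipping,
# dense enumeration) rather than calling package internals.

# exhaustive interior-face scan: total boundary length of a logical mask
face_scan_length <- function(mask, cell_size = 10, valid = NULL) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (is.null(valid)) valid <- matrix(TRUE, nr, nc)
  len <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (c < nc && valid[r, c] && valid[r, c + 1] &&
        mask[r, c] != mask[r, c + 1]) len <- len + cell_size
    if (r < nr && valid[r, c] && valid[r + 1, c] &&
        mask[r, c] != mask[r + 1, c]) len <- len + cell_size
  }
  len
}

# closed-square segment/cell intersection by dense parameter sampling plus
# endpoint checks (adequate for unit-scale test segments)
segment_touches_cell_sampled <- function(p1, p2, xlo, xhi, ylo, yhi,
                                         n = 4001) {
  t <- seq(0, 1, length.out = n)
  x <- p1[1] + t * (p2[1] - p1[1])
  y <- p1[2] + t * (p2[2] - p1[2])
  any(x >= xlo - 1e-9 & x <= xhi + 1e-9 & y >= ylo - 1e-9 & y <= yhi + 1e-9)
}

# clipped-in-disc length by fine sampling of each segment
sampled_length_in_disc <- function(segments, center, radius, step = 0.01) {
  tot <- 0
  for (i in seq_len(nrow(segments))) {
    p1 <- segments[i, 1:2]; p2 <- segments[i, 3:4]
    len <- sqrt(sum((p2 - p1)^2))
    n <- max(ceiling(len / step), 1)
    t <- (seq_len(n) - 0.5) / n
    x <- p1[1] + t * (p2[1] - p1[1])
    y <- p1[2] + t * (p2[2] - p1[2])
    inside <- (x - center[1])^2 + (y - center[2])^2 <= radius^2
    tot <- tot + mean(inside) * len
  }
  tot
}

# direct 2J/(A+B) on presence vectors
bc_similarity_direct <- function(a, b, dummy = FALSE) {
  A <- sum(a > 0) + dummy
  B <- sum(b > 0) + dummy
  J <- sum(a > 0 & b > 0) + dummy
  if (A + B == 0) return(NA_real_)
  2 * J / (A + B)
}

# tiny random land-cover grid over the given codes
random_landcover <- function(nr, nc, codes = c(6L, 7L), cell_size = 10) {
  land_cover_grid(matrix(sample(codes, nr * nc, replace = TRUE), nr, nc),
                  cell_size)
}

# minimal pair data with crossed site random effects for decay-model tests;
# mu_fun maps distance (km) to the mean response
simulate_pairs <- function(n_sites, mu_fun, sd_site = 0.04, sd_res = 0.08,
                           extent_km = 80, country = "pooled") {
  xy <- cbind(runif(n_sites, 0, extent_km), runif(n_sites, 0, extent_km))
  cmb <- utils::combn(n_sites, 2)
  i <- cmb[1, ]; j <- cmb[2, ]
  d <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
  re <- rnorm(n_sites, 0, sd_site)
  data.frame(site_i = sprintf("S%02d", i), site_j = sprintf("S%02d", j),
             country = country, geo_km = d,
             sim_all = mu_fun(d) + re[i] + re[j] + rnorm(length(d), 0, sd_res))
}
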