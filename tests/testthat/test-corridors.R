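test_that("edge weights scale with neighbour distance and mean conductance", {
  # 1x2 grid of full conductance: one edge, cost 1
  g <- conductance_graph(proportion_grid(matrix(1, 1, 2), 100))
  e <- graph_edges(g)
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, 1)
  # 2x2 all ones: rook edges cost 1, diagonal edges cost sqrt(2)
  g2 <- conductance_graph(proportion_grid(matrix(1, 2, 2), 100))
  e2 <- graph_edges(g2)
  expect_equal(sort(e2$weight), sort(c(1, 1, 1, 1, sqrt(2), sqrt(2))))
})

test_that("the edge list matches a brute-force 8-neighbour enumeration", {
  set.seed(31)
  x <- matrix(runif(9, 0.1, 1), 3, 3)
  g <- conductance_graph(proportion_grid(x, 100))
  e <- graph_edges(g)
  # brute force: every in-bounds 8-neighbour pair once
  id <- function(r, c) (r - 1) * 3 + c
  exp <- list()
  for (r in 1:3) for (c in 1:3) for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > 3 || c2 < 1 || c2 > 3) next
    a <- id(r, c); b <- id(r2, c2)
    if (a < b)
      exp[[paste(a, b)]] <- c(a, b, sqrt(dr^2 + dc^2) /
                                (0.5 * (x[r, c] + x[r2, c2])))
  }
  exp <- do.call(rbind, exp[order(names(exp))])
  expect_equal(nrow(e), nrow(exp))
  key <- order(e$from, e$to)
  ekey <- order(exp[, 1], exp[, 2])
  expect_equal(e$from[key], unname(exp[ekey, 1]))
  expect_equal(e$to[key], unname(exp[ekey, 2]))
  expect_equal(e$weight[key], unname(exp[ekey, 3]))
})

test_that("least-cost paths achieve the brute-force optimum on small grids", {
  set.seed(32)
  for (rep in 1:40) {
    dims <- if (rep %% 2) c(3, 3) else c(4, 4)
    x <- matrix(runif(prod(dims)), dims[1], dims[2])
    x[runif(length(x)) < 0.2] <- 0          # exercise the eps floor
    pg <- proportion_grid(x, 100)
    g <- conductance_graph(pg)
    src <- c(1, 1); dst <- dims
    p <- least_cost_path(g, src, dst)
    bf <- beecorridors:::min_path_cost_bruteforce(
      x, 1e-6, 1L, as.integer((dims[1] - 1) * dims[2] + dims[2]))
    expect_identical(p$graph_cost, bf)
  }
})

test_that("least-cost paths agree with igraph on random grids", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (rep in 1:5) {
    x <- matrix(runif(36, 0.05, 1), 6, 6)
    g <- conductance_graph(proportion_grid(x, 100))
    e <- graph_edges(g)
    ig <- igraph::graph_from_data_frame(e, directed = FALSE,
                                        vertices = data.frame(name = 1:36))
    d_ig <- igraph::distances(ig, v = "1", to = "36", weights = e$weight)
    p <- least_cost_path(g, c(1, 1), c(6, 6))
    expect_equal(p$graph_cost, as.numeric(d_ig), tolerance = 1e-12)
  }
})

test_that("paths hug high-conductance structure instead of cutting across", {
  x <- matrix(1e-6, 3, 3)
  x[3, ] <- 1       # top row (row 3 = north) ...
  x[, 1] <- 1       # ... and left column form an L of habitat
  g <- conductance_graph(proportion_grid(x, 100))
  p <- least_cost_path(g, c(3, 3), c(1, 1))
  # the optimal route follows the L: along the top row then down the left
  # column (with the diagonal shortcut between the two arms), never the
  # straight diagonal across the empty matrix
  expect_true(all(p$cells[, 1] == 3 | p$cells[, 2] == 1))
  expect_identical(p$graph_cost,
                   beecorridors:::min_path_cost_bruteforce(x, 1e-6, 9L, 1L))
})

test_that("degenerate and symmetric path cases behave", {
  x <- matrix(c(0.2, 0.6, 0.9, 0.4), 2, 2)
  g <- conductance_graph(proportion_grid(x, 100))
  p <- least_cost_path(g, c(1, 1), c(1, 1))
  expect_equal(nrow(p$cells), 1)
  expect_equal(p$length_m, 0)
  expect_equal(p$cost, 1 - x[1, 1])
  # symmetry of optimal cost
  p1 <- least_cost_path(g, c(1, 1), c(2, 2))
  p2 <- least_cost_path(g, c(2, 2), c(1, 1))
  expect_equal(p1$graph_cost, p2$graph_cost)
})

test_that("corridor metrics sum steps and 1 - x over path cells", {
  x <- matrix(1, 1, 5)
  g <- conductance_graph(proportion_grid(x, 100))
  p <- least_cost_path(g, c(1, 1), c(1, 5))
  m <- corridor_metrics(p, g$grid)
  expect_equal(m$length_km, 0.4)
  expect_equal(m$cost, 0)
  x2 <- matrix(0.5, 1, 5)
  g2 <- conductance_graph(proportion_grid(x2, 100))
  p2 <- least_cost_path(g2, c(1, 1), c(1, 5))
  expect_equal(corridor_metrics(p2, g2$grid)$cost, 2.5)
  # independent per-step recomputation on a random 4x4 path
  set.seed(34)
  x3 <- matrix(runif(16, 0.1, 1), 4, 4)
  g3 <- conductance_graph(proportion_grid(x3, 100))
  p3 <- least_cost_path(g3, c(1, 1), c(4, 3))
  steps <- diff(p3$cells)
  len <- sum(sqrt(steps[, 1]^2 + steps[, 2]^2)) * 100 / 1000
  expect_equal(corridor_metrics(p3, g3$grid)$length_km, len)
  expect_equal(corridor_metrics(p3, g3$grid)$cost,
               sum(1 - x3[p3$cells]))
})

test_that("geographic distance is Euclidean in km", {
  expect_equal(geographic_distance(c(0, 0), c(3000, 4000)), 5)
  expect_equal(geographic_distance(c(10, 10), c(10, 10)), 0)
  set.seed(35)
  p1 <- matrix(runif(10, 0, 1e5), ncol = 2)
  p2 <- matrix(runif(10, 0, 1e5), ncol = 2)
  expect_equal(geographic_distance(p1, p2),
               sqrt(rowSums((p1 - p2)^2)) / 1000)
})

test_that("pairwise distances cover within-country pairs and dominate geography", {
  set.seed(36)
  sites <- site_table(paste0("S", 1:5),
                      x = c(150, 450, 850, 250, 750),
                      y = c(150, 550, 250, 850, 750),
                      country = c("a", "a", "a", "b", "b"),
                      plant_richness = 5)
  x <- matrix(runif(100, 0, 1), 10, 10)
  pg <- proportion_grid(x, 100)
  pd <- pairwise_distances(sites, list(lls = pg))
  expect_equal(nrow(pd), choose(3, 2) + choose(2, 2))
  # lcp length >= geographic distance between snapped centres (one diagonal slack)
  expect_true(all(pd$lcp_len_lls_km >= pd$geo_km - 2 * 100 * sqrt(2) / 1000))
  # coincident-cell sites give zero-length paths
  s2 <- site_table(c("P", "Q"), c(120, 140), c(120, 140), "a", 1)
  pd2 <- pairwise_distances(s2, list(lls = pg))
  expect_equal(pd2$lcp_len_lls_km, 0)
  # sites outside the raster are named in the error
  s3 <- site_table(c("P", "Q"), c(120, 9999), c(120, 140), "a", 1)
  expect_error(pairwise_distances(s3, list(lls = pg)), "Q")
})

test_that("raising conductance never worsens the optimal cost", {
  set.seed(37)
  for (rep in 1:10) {
    x <- matrix(runif(16, 0.05, 0.9), 4, 4)
    g <- conductance_graph(proportion_grid(x, 100))
    base <- least_cost_path(g, c(1, 1), c(4, 4))$graph_cost
    cell <- sample(16, 1)
    x2 <- x; x2[cell] <- min(x[cell] + 0.3, 1)
    g2 <- conductance_graph(proportion_grid(x2, 100))
    expect_lte(least_cost_path(g2, c(1, 1), c(4, 4))$graph_cost, base)
  }
})
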