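test_that("AICc applies the small-sample correction and converges to AIC", {
  expect_equal(aicc_value(-10, 3, 20), 26 + 2 * 3 * 4 / 16)
  expect_gt(aicc_value(-10, 3, 20), -2 * -10 + 2 * 3)
  expect_equal(aicc_value(-10, 3, 1e8), 26, tolerance = 1e-5)
  expect_equal(aicc_value(-10, 3, 4), Inf)   # n <= k + 1
  expect_error(aicc_value(-10, 0, 20), "k must be")
})

test_that("the Poisson GLM recovers closed-form fits and a tiny score norm", {
  d <- data.frame(y = c(1, 2, 3))
  f <- fit_poisson_glm(y ~ 1, d)
  expect_equal(unname(coef(f)), log(2), tolerance = 1e-8)
  # closed-form Poisson log-likelihood at the mean
  ll <- sum(d$y * log(2) - 2 - lfactorial(d$y))
  expect_equal(as.numeric(logLik(f)), ll, tolerance = 1e-8)
  # binary covariate: coefficient = log ratio of group means
  d2 <- data.frame(y = c(2, 4, 3, 9, 11, 10), g = rep(0:1, each = 3))
  f2 <- fit_poisson_glm(y ~ g, d2)
  expect_equal(unname(coef(f2)["g"]), log(10 / 3), tolerance = 1e-8)
  # score vector ~ 0 at the optimum for a random design
  set.seed(51)
  X <- cbind(1, scale(matrix(rnorm(200 * 3), 200, 3)))
  beta <- c(1, 0.3, -0.2, 0.1)
  d3 <- data.frame(y = rpois(200, exp(X %*% beta)),
                   x1 = X[, 2], x2 = X[, 3], x3 = X[, 4])
  f3 <- fit_poisson_glm(y ~ x1 + x2 + x3, d3)
  score <- crossprod(X, d3$y - fitted(f3))
  expect_lt(sqrt(sum(score^2)), 1e-6)
  # canonical-link property: fitted sum equals response sum
  expect_equal(sum(fitted(f3)), sum(d3$y))
})

test_that("rank-deficient designs error with the aliased column named", {
  d <- data.frame(y = rpois(20, 3), a = rnorm(20))
  d$b <- d$a
  expect_error(fit_poisson_glm(y ~ a + b, d), "b")
})

test_that("the likelihood-ratio test equals the deviance difference", {
  set.seed(52)
  d <- data.frame(y = rpois(100, 5), x = rnorm(100), z = rnorm(100))
  full <- fit_poisson_glm(y ~ x + z, d)
  res <- lrt_drop1(full, "z")
  red <- fit_poisson_glm(y ~ x, d)
  expect_equal(res$statistic, red$deviance - full$deviance, tolerance = 1e-7)
  expect_equal(res$df, 1)
  expect_error(lrt_drop1(full, "nope"), "not in the model")
  # dropping an interaction keeps the main effects
  d$w <- rnorm(100)
  f2 <- fit_poisson_glm(y ~ x * w, d)
  r2 <- lrt_drop1(f2, "x:w")
  red2 <- fit_poisson_glm(y ~ x + w, d)
  expect_equal(r2$statistic,
               2 * (as.numeric(logLik(f2)) - as.numeric(logLik(red2))),
               tolerance = 1e-7)
})

test_that("radius selection takes the AICc minimum with ties to smaller radii", {
  tab <- data.frame(radius = c(250, 500, 750),
                    all = c(373.4, 378.1, 375.0),
                    forest = c(372.5, 372.5, 380.0))
  sel <- select_radius(tab)
  expect_equal(sel$all$radius, 250)
  expect_equal(sel$forest$radius, 250)  # tie resolves to smaller radius
  expect_equal(sel$all$aicc, 373.4)
})

test_that("radius selection recovers the generating spatial scale", {
  # richness generated from the 1000-m LLS covariate should not select a
  # distant radius
  set.seed(53)
  hits <- 0L
  for (rep in 1:10) {
    cfg <- scenario_config(seed = 5300 + rep, dim = c(500L, 500L),
                           n_sites = c(8L, 8L))
    set.seed(cfg$seed)
    grid <- simulate_landscape(cfg)
    sites <- simulate_sites(cfg, grid)
    lls <- extract_boundaries(grid, seminatural_class_sets())
    forest <- extract_boundaries(grid, list(c(2L, 3L)))
    met <- site_landscape_metrics(sites, lls, forest, grid)
    l1000 <- met$lls_all_m[met$radius == 1000]
    mu <- exp(1.6 + 0.8 * scale(log(l1000 + 1)))
    rich <- rpois(length(mu), mu)
    fits <- fit_richness_models(sites, met, richness = rich)
    sel <- select_radius(fits$aicc_table)
    if (abs(sel$all$radius - 1000) <= 250) hits <- hits + 1L
  }
  expect_gte(hits, 6)
})

test_that("Moran's I matches the hand-computed statistic on 3 points", {
  # equilateral triangle: equal weights 1/2 after row-normalization
  coords <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)) * 100
  z <- c(1, -0.5, -0.5)
  res <- morans_i(z, coords)
  # I = (1/sum(w)) * sum_ij w_ij z_i z_j / (sum z^2 / n), computed by hand
  w <- 1 / as.matrix(dist(coords)); diag(w) <- 0; w <- w / rowSums(w)
  num <- as.numeric(t(z) %*% w %*% z)
  I_hand <- (3 / sum(w)) * num / sum(z^2)
  expect_equal(res$observed, I_hand)
  expect_equal(res$expected, -1 / 2)
  expect_error(morans_i(c(1, 1, 1), coords), "constant")
  expect_error(morans_i(z, coords[c(1, 1, 2), ]), "coincident")
  expect_error(morans_i(z[1:2], coords[1:2, ]), "at least 3")
})

test_that("Moran's I of spatially random residuals centres on -1/(n-1)", {
  set.seed(54)
  n <- 30
  coords <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  Is <- replicate(200, morans_i(rnorm(n), coords)$observed)
  se <- sd(Is) / sqrt(length(Is))
  expect_lt(abs(mean(Is) - (-1 / (n - 1))), 4 * se + 0.01)
})

test_that("the dispersion ratio flags overdispersion and not clean Poisson", {
  set.seed(55)
  d <- data.frame(x = rnorm(200))
  d$y <- rpois(200, exp(1 + 0.3 * d$x))
  f <- fit_poisson_glm(y ~ x, d)
  r <- dispersion_check(f)
  expect_lt(abs(r$ratio - 1), 0.25)
  expect_false(r$overdispersed)
  # negative binomial data fit as Poisson overdisperses
  d$y2 <- rnbinom(200, mu = exp(1 + 0.3 * d$x), size = 0.8)
  r2 <- dispersion_check(fit_poisson_glm(y2 ~ x, d))
  expect_gt(r2$ratio, 1.5)
  expect_true(r2$overdispersed)
})
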