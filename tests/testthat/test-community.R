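make_traits <- function() {
  species_traits(c("A_parasite", "B_one", "B_two", "C_sol", "D_sol"),
                 parasitic = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                 group = c("solitary", "bumblebee", "bumblebee",
                           "solitary", "solitary"),
                 cryptic_complex = c(NA, "B_cx", "B_cx", NA, NA))
}

test_that("curation drops parasites and pools cryptic complexes", {
  occ <- occurrence_table(matrix(
    c(2, 1, 0, 3, 1,
      0, 0, 4, 1, 0), nrow = 2, byrow = TRUE,
    dimnames = list(c("s1", "s2"),
                    c("A_parasite", "B_one", "B_two", "C_sol", "D_sol"))))
  cur <- curate(occ, make_traits())
  expect_equal(colnames(cur), c("B_cx", "C_sol", "D_sol"))   # alphabetical
  expect_equal(unname(cur["s1", "B_cx"]), 1L)                # 1 + 0
  expect_equal(unname(cur["s2", "B_cx"]), 4L)
  # total non-parasitic occurrences conserved under pooling
  expect_equal(sum(cur), sum(unclass(occ)[, -1]))
  # identity when nothing to drop or pool
  tr2 <- species_traits(c("x", "y"), FALSE, "solitary")
  occ2 <- occurrence_table(matrix(1:4, 2, dimnames = list(c("s1", "s2"),
                                                          c("x", "y"))))
  expect_equal(unclass(curate(occ2, tr2)), unclass(occ2), ignore_attr = TRUE)
  expect_error(curate(occ2, make_traits()), "missing from traits")
})

test_that("richness counts species with positive counts per site", {
  occ <- occurrence_table(matrix(c(0, 0, 0, 2, 1, 0), 2,
                                 dimnames = list(c("s1", "s2"),
                                                 c("a", "b", "c"))))
  expect_equal(site_richness(occ), c(s1 = 1L, s2 = 1L))
  empty <- occurrence_table(matrix(0L, 2, 3,
                                   dimnames = list(c("s1", "s2"),
                                                   c("a", "b", "c"))))
  expect_equal(unname(site_richness(empty)), c(0L, 0L))
  set.seed(41)
  m <- matrix(rpois(60, 0.7), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("sp", 1:10)))
  expect_equal(unname(site_richness(occurrence_table(m))),
               unname(rowSums(m > 0)))
})

test_that("Bray-Curtis similarity follows 2J/(A+B) and the dummy rescues empties", {
  m <- matrix(0L, 2, 5, dimnames = list(c("i", "j"), letters[1:5]))
  m[1, 1:3] <- 1L          # A = 3
  m[2, c(3, 5)] <- 1L      # B = 2, J = 1
  occ <- occurrence_table(m)
  expect_equal(bray_curtis_similarity(occ, "i", "j"), 0.4)  # 1 - 3/5
  # identical nonempty communities
  m2 <- m; m2[2, ] <- m2[1, ]
  expect_equal(bray_curtis_similarity(occurrence_table(m2), 1, 2), 1)
  # empty pair: undefined without the dummy, 1 with it
  e <- occurrence_table(matrix(0L, 2, 4, dimnames = list(c("i", "j"),
                                                         letters[1:4])))
  expect_true(is.na(bray_curtis_similarity(e, 1, 2)))
  expect_equal(bray_curtis_similarity(e, 1, 2, dummy = TRUE), 1)
})

test_that("similarity matches vegan and the direct formula on random tables", {
  skip_if_not_installed("vegan")
  set.seed(42)
  for (rep in 1:20) {
    m <- matrix(rbinom(50, 1, runif(1, 0.2, 0.7)), 5, 10,
                dimnames = list(paste0("s", 1:5), paste0("sp", 1:10)))
    occ <- occurrence_table(m)
    S <- similarity_matrix(occ)
    for (i in 1:4) for (j in (i + 1):5) {
      direct <- bc_similarity_direct(m[i, ], m[j, ])
      expect_identical(S[i, j], S[j, i])
      expect_equal(S[i, j], direct)
      if (!is.na(direct) && sum(m[i, ]) > 0 && sum(m[j, ]) > 0) {
        v <- 1 - as.numeric(vegan::vegdist(m[c(i, j), ], method = "bray",
                                           binary = TRUE))
        expect_equal(S[i, j], v)
      }
    }
  }
})

test_that("adding shared species raises similarity; unshared lowers it", {
  set.seed(43)
  m <- matrix(rbinom(20, 1, 0.5), 2, 10,
              dimnames = list(c("i", "j"), paste0("sp", 1:10)))
  m[1, 1] <- 1  # nonempty
  base <- bc_similarity_direct(m[1, ], m[2, ])
  shared <- cbind(m, both = c(1, 1))
  one <- cbind(m, only_i = c(1, 0))
  expect_gte(bc_similarity_direct(shared[1, ], shared[2, ]), base)
  expect_lte(bc_similarity_direct(one[1, ], one[2, ]), base)
})

test_that("the pair table is symmetric, covers same-country pairs, and joins covariates", {
  set.seed(44)
  sites <- site_table(paste0("S", 1:6),
                      x = runif(6, 100, 900), y = runif(6, 100, 900),
                      country = rep(c("a", "b"), each = 3),
                      plant_richness = rpois(6, 8))
  pg <- proportion_grid(matrix(runif(100, 0.1, 1), 10, 10), 100)
  dists <- pairwise_distances(sites, list(lls = pg, forest = pg))
  traits <- species_traits(paste0("bee", 1:8),
                           parasitic = FALSE,
                           group = rep(c("bumblebee", "solitary"), each = 4))
  bees <- occurrence_table(matrix(rbinom(48, 1, 0.5), 6, 8,
                                  dimnames = list(sites$id, traits$species)))
  plants <- occurrence_table(matrix(rbinom(36, 1, 0.6), 6, 6,
                                    dimnames = list(sites$id,
                                                    paste0("pl", 1:6))))
  pt <- build_pair_table(sites, bees, plants, traits, dists)
  expect_equal(nrow(pt), 2 * choose(3, 2))
  expect_true(all(pt$sim_all >= 0 & pt$sim_all <= 1, na.rm = TRUE))
  expect_true(all(pt$sim_solitary >= 0 & pt$sim_solitary <= 1))
  # solitary similarity uses only solitary species, with the dummy
  sol <- unclass(bees)[, 5:8]
  k <- 3  # a within-country pair row
  exp_sol <- bc_similarity_direct(sol[pt$site_i[k], ], sol[pt$site_j[k], ],
                                  dummy = TRUE)
  expect_equal(pt$sim_solitary[k], exp_sol)
  # symmetric under i/j swap by construction of the similarity matrix
  S <- similarity_matrix(bees)
  expect_equal(pt$sim_all, S[cbind(pt$site_i, pt$site_j)])
  expect_equal(pt$sim_all, S[cbind(pt$site_j, pt$site_i)])
  # plant richness joined per site
  expect_equal(pt$plantSR_i,
               sites$plant_richness[match(pt$site_i, sites$id)])
  expect_error(build_pair_table(sites, bees[1:3, ], plants, traits, dists),
               "missing")
})
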