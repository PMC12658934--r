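#' Occurrence table
#'
#' Sites x species matrix of occurrence counts. Presence-based analyses
#' use `count > 0`; counts are retained for simulation and future
#' abundance-based variants.
#'
#' @param counts Non-negative integer matrix with site ids as row names
#'   and species names as column names, or a long data frame with
#'   columns `site`, `species`, `count`.
#' @param sites Optional site id vector fixing row order (and adding
#'   empty rows for unobserved sites).
#' @return Integer matrix of class `occurrence_table`.
#' @export
occurrence_table <- function(counts, sites = NULL) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("site", "species") %in% names(counts)))
    if (is.null(counts$count)) counts$count <- 1L
    sids <- if (is.null(sites)) sort(unique(counts$site)) else as.character(sites)
    spp <- sort(unique(counts$species))
    m <- matrix(0L, length(sids), length(spp), dimnames = list(sids, spp))
    for (k in seq_len(nrow(counts)))
      m[as.character(counts$site[k]), as.character(counts$species[k])] <-
        m[as.character(counts$site[k]), as.character(counts$species[k])] +
        as.integer(counts$count[k])
    counts <- m
  } else {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (!is.null(sites)) {
      m <- matrix(0L, length(sites), ncol(counts),
                  dimnames = list(as.character(sites), colnames(counts)))
      common <- intersect(rownames(counts), rownames(m))
      m[common, ] <- counts[common, ]
      counts <- m
    }
  }
  if (any(counts < 0)) stop("occurrence counts must be >= 0")
  class(counts) <- c("occurrence_table", class(counts))
  counts
}

#' Species trait table
#'
#' @param species Species names.
#' @param parasitic Logical kleptoparasite flag.
#' @param group `"bumblebee"` or `"solitary"` (ignored for plants).
#' @param cryptic_complex Optional label pooling morphologically
#'   inseparable species into one morphospecies (`NA` = none).
#' @return Data frame of class `species_traits`.
#' @export
species_traits <- function(species, parasitic = FALSE, group = "solitary",
                           cryptic_complex = NA_character_) {
  out <- data.frame(species = as.character(species),
                    parasitic = as.logical(parasitic),
                    group = as.character(group),
                    cryptic_complex = as.character(cryptic_complex),
                    stringsAsFactors = FALSE)
  class(out) <- c("species_traits", "data.frame")
  out
}

#' Curate an occurrence table
#'
#' Drops kleptoparasitic species (their distribution tracks hosts, not
#' habitat) and pools every cryptic complex into a single morphospecies
#' column named after the complex. Output columns are alphabetical.
#'
#' @param occ An `occurrence_table`.
#' @param traits A `species_traits` table covering every species in `occ`.
#' @return Curated `occurrence_table`.
#' @export
curate <- function(occ, traits) {
  spp <- colnames(occ)
  missing <- setdiff(spp, traits$species)
  if (length(missing))
    stop("species missing from traits: ", paste(missing, collapse = ", "))
  tr <- traits[match(spp, traits$species), ]
  keep <- !tr$parasitic
  m <- unclass(occ)[, keep, drop = FALSE]
  cx <- tr$cryptic_complex[keep]
  has_cx <- !is.na(cx)
  if (any(has_cx)) {
    groups <- ifelse(has_cx, cx, colnames(m))
    pooled <- t(rowsum(t(m), groups))
    m <- pooled
  }
  m <- m[, order(colnames(m)), drop = FALSE]
  storage.mode(m) <- "integer"
  class(m) <- c("occurrence_table", class(m))
  m
}

#' Per-site species richness
#'
#' @param occ An `occurrence_table` (usually curated).
#' @return Named integer vector: number of species with count > 0 per site.
#' @export
site_richness <- function(occ) {
  r <- rowSums(unclass(occ) > 0)
  storage.mode(r) <- "integer"
  r
}

#' Binary Bray-Curtis compositional similarity between two sites
#'
#' On presence-absence data, with per-site richnesses A and B and J
#' shared species, the Bray-Curtis dissimilarity is (A+B-2J)/(A+B) and
#' the similarity `1 - BC = 2J/(A+B)`. With `dummy = TRUE` an artificial
#' species present at every site is added (A, B and J each incremented
#' by 1), keeping the index defined for empty communities and damping
#' zero inflation in sparse ones.
#'
#' @param occ An `occurrence_table`.
#' @param i,j Site ids or row indices.
#' @param dummy Add the dummy species shared by all sites?
#' @return Similarity in \[0, 1\]; `NA` when both communities are empty
#'   and `dummy = FALSE`.
#' @export
bray_curtis_similarity <- function(occ, i, j, dummy = FALSE) {
  m <- unclass(occ) > 0
  pi <- m[i, ]; pj <- m[j, ]
  A <- sum(pi) + dummy
  B <- sum(pj) + dummy
  J <- sum(pi & pj) + dummy
  if (A + B == 0) return(NA_real_)
  2 * J / (A + B)
}

#' All-pairs Bray-Curtis similarity matrix
#'
#' @inheritParams bray_curtis_similarity
#' @return Symmetric sites x sites similarity matrix.
#' @export
similarity_matrix <- function(occ, dummy = FALSE) {
  m <- (unclass(occ) > 0) + 0
  J <- m %*% t(m) + dummy
  A <- rowSums(m) + dummy
  tot <- outer(A, A, "+")
  s <- 2 * J / tot
  s[tot == 0] <- NA_real_
  dimnames(s) <- list(rownames(occ), rownames(occ))
  s
}

#' Assemble the pairwise site table for distance-decay models
#'
#' One record per unordered within-country site pair, carrying bee
#' compositional similarity (all species, and solitary bees only with
#' the dummy species), plant compositional similarity, plant richness of
#' both sites, and all distance measures from [pairwise_distances()].
#'
#' @param sites A `site_table`.
#' @param occ_bees Curated bee `occurrence_table`.
#' @param occ_plants Plant `occurrence_table`.
#' @param traits Bee `species_traits` (for the bumblebee/solitary split;
#'   pooled morphospecies inherit the group of their members).
#' @param dists Pair table from [pairwise_distances()].
#' @return Data frame of pair records.
#' @export
build_pair_table <- function(sites, occ_bees, occ_plants, traits, dists) {
  need <- unique(c(dists$site_i, dists$site_j))
  for (tb in list(occ_bees, occ_plants)) {
    miss <- setdiff(need, rownames(tb))
    if (length(miss))
      stop("sites missing from an occurrence table: ",
           paste(miss, collapse = ", "))
  }
  sol_species <- species_group_columns(colnames(occ_bees), traits, "solitary")
  occ_sol <- unclass(occ_bees)[, sol_species, drop = FALSE]
  sim_all <- similarity_matrix(occ_bees, dummy = FALSE)
  sim_sol <- similarity_matrix(occ_sol, dummy = TRUE)
  sim_pla <- similarity_matrix(occ_plants, dummy = FALSE)
  out <- dists
  i <- out$site_i; j <- out$site_j
  out$sim_all <- sim_all[cbind(i, j)]
  out$sim_solitary <- sim_sol[cbind(i, j)]
  out$sim_plants <- sim_pla[cbind(i, j)]
  si <- match(i, sites$id); sj <- match(j, sites$id)
  if (anyNA(si) || anyNA(sj)) stop("pair table references unknown sites")
  out$plantSR_i <- sites$plant_richness[si]
  out$plantSR_j <- sites$plant_richness[sj]
  out
}

# map (possibly pooled) occurrence columns to a bee group
species_group_columns <- function(cols, traits, group) {
  grp <- vapply(cols, function(sp) {
    hit <- traits$species == sp
    if (any(hit)) return(traits$group[hit][1])
    cx <- !is.na(traits$cryptic_complex) & traits$cryptic_complex == sp
    if (any(cx)) return(traits$group[cx][1])
    NA_character_
  }, character(1))
  if (anyNA(grp))
    stop("no trait group for species: ",
         paste(cols[is.na(grp)], collapse = ", "))
  cols[grp == group]
}
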