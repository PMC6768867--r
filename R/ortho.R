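#' Validate an orthogroup map
#'
#' A long-format two-species orthology map: one row per (orthogroup, species,
#' gene). Both one-to-one and many-to-many associations are representable;
#' each gene may belong to exactly one orthogroup.
#'
#' @param map data.frame with columns `orthogroup_id`, `species`, `gene_id`.
#' @return the validated map (class `orthogroup_map`).
#' @export
orthogroup_map <- function(map) {
  stopifnot(all(c("orthogroup_id", "species", "gene_id") %in% names(map)))
  dup <- duplicated(map[, c("species", "gene_id")])
  if (any(dup)) stop("a gene may belong to exactly one orthogroup")
  class(map) <- c("orthogroup_map", "data.frame")
  map
}

#' Map a gene set to its orthogroups
#'
#' @param gene_set character vector of gene ids.
#' @param species species label present in the map.
#' @param map orthogroup map data.frame.
#' @return character vector of orthogroup ids containing at least one member
#'   of the set, with attribute `n_unmapped` counting genes absent from the
#'   map.
#' @export
genes_to_orthogroups <- function(gene_set, species, map) {
  if (!species %in% map$species) stop("unknown species: ", species)
  m <- map[map$species == species, , drop = FALSE]
  hit <- match(gene_set, m$gene_id)
  out <- sort(unique(m$orthogroup_id[hit[!is.na(hit)]]))
  attr(out, "n_unmapped") <- sum(is.na(hit))
  out
}

## orthogroup incidence overlap counts for a block of Monte Carlo draws:
## draws n genes per iteration (with or without replacement) from each
## species' universe, maps to integer orthogroup codes (NA = gene outside
## the map, hitting nothing), and counts orthogroups hit by both draws
.mc_overlap_block <- function(og_a, og_b, n1, n2, n_iter, K, replace) {
  ha <- matrix(FALSE, n_iter, K)
  hb <- matrix(FALSE, n_iter, K)
  if (replace) {
    ia <- sample.int(length(og_a), n_iter * n1, replace = TRUE)
    ib <- sample.int(length(og_b), n_iter * n2, replace = TRUE)
  } else {
    ia <- as.vector(vapply(seq_len(n_iter), function(i)
      sample.int(length(og_a), n1), integer(n1)))
    ib <- as.vector(vapply(seq_len(n_iter), function(i)
      sample.int(length(og_b), n2), integer(n2)))
  }
  oa <- og_a[ia]
  ob <- og_b[ib]
  ra <- rep(seq_len(n_iter), times = n1)
  rb <- rep(seq_len(n_iter), times = n2)
  ha[cbind(ra[!is.na(oa)], oa[!is.na(oa)])] <- TRUE
  hb[cbind(rb[!is.na(ob)], ob[!is.na(ob)])] <- TRUE
  rowSums(ha & hb)
}

#' Monte Carlo orthogroup-level overlap test
#'
#' Tests whether the observed number of orthogroups shared between two
#' species' gene sets exceeds chance. The observed statistic t* is the size
#' of the intersection of the two sets' orthogroup images. The null is built
#' by repeatedly (M times) drawing n1 genes from species A's universe and n2
#' from species B's (with replacement by default), mapping each draw to
#' orthogroups and recording the overlap t_i. The p-value is the
#' add-one-smoothed tail frequency
#' `(1 + sum(t_i >= t*)) / (1 + M)`,
#' so p lies in \[1/(1+M), 1\]. A plain (gene-level) hypergeometric test is
#' not appropriate here because orthogroups contain multiple genes per
#' species.
#'
#' @param set_a,set_b gene sets for the two species.
#' @param species_a,species_b species labels in the map.
#' @param map orthogroup map data.frame.
#' @param M number of Monte Carlo iterations (default 1e5).
#' @param seed RNG seed.
#' @param replace draw with replacement (the default, matching the stated
#'   procedure); set FALSE for a without-replacement sensitivity analysis.
#' @param universes optional named list of custom per-species gene universes
#'   (e.g. the full measured transcriptome); defaults to the map-covered
#'   genes of each species. Universe genes outside the map may be drawn and
#'   hit no orthogroup. Draw sizes n1, n2 are the input gene-set sizes.
#' @return object of class `mc_overlap`: t_star, n1, n2, M, p_estimate, a
#'   summary of the null overlap distribution, and the shared orthogroups.
#' @export
mc_overlap_test <- function(set_a, species_a, set_b, species_b, map,
                            M = 1e5, seed = NULL, replace = TRUE,
                            universes = NULL) {
  if (M < 1) stop("M must be at least 1")
  og_obs_a <- genes_to_orthogroups(set_a, species_a, map)
  og_obs_b <- genes_to_orthogroups(set_b, species_b, map)
  shared <- intersect(og_obs_a, og_obs_b)
  t_star <- length(shared)

  if (is.null(universes)) {
    universes <- list(
      map$gene_id[map$species == species_a],
      map$gene_id[map$species == species_b])
  } else {
    universes <- list(universes[[species_a]], universes[[species_b]])
  }
  og_levels <- sort(unique(map$orthogroup_id))
  K <- length(og_levels)
  code <- function(univ, sp) {
    m <- map[map$species == sp, , drop = FALSE]
    # genes in the universe but outside the map are legitimate: they can be
    # drawn, and hit no orthogroup
    match(m$orthogroup_id[match(univ, m$gene_id)], og_levels)
  }
  og_a <- code(universes[[1]], species_a)
  og_b <- code(universes[[2]], species_b)

  # draw sizes are the input gene-set sizes, as in the stated procedure
  n1 <- length(set_a)
  n2 <- length(set_b)
  if (n1 < 1 || n2 < 1) stop("both sets need at least one gene")

  if (!is.null(seed)) set.seed(seed)
  block <- max(1, min(2000, ceiling(2e6 / K)))
  t_null <- integer(0)
  left <- M
  while (left > 0) {
    nb <- min(block, left)
    t_null <- c(t_null, .mc_overlap_block(og_a, og_b, n1, n2, nb, K, replace))
    left <- left - nb
  }
  p <- (1 + sum(t_null >= t_star)) / (1 + M)
  structure(list(
    t_star = t_star, n1 = n1, n2 = n2, M = M, p_estimate = p,
    shared_orthogroups = shared,
    null_overlaps = list(mean = mean(t_null), sd = sd(t_null),
                         max = max(t_null),
                         quantiles = quantile(t_null, c(.5, .95, .99)),
                         tabulated = tabulate(t_null + 1L)),
    n_unmapped = c(a = attr(og_obs_a, "n_unmapped"),
                   b = attr(og_obs_b, "n_unmapped")),
    replace = replace, seed = seed), class = "mc_overlap")
}

#' @export
print.mc_overlap <- function(x, ...) {
  cat("Monte Carlo orthogroup overlap test\n")
  cat(sprintf("  t* = %d shared orthogroups (n1 = %d, n2 = %d genes)\n",
              x$t_star, x$n1, x$n2))
  cat(sprintf("  null mean %.2f (sd %.2f, max %d) over M = %g draws%s\n",
              x$null_overlaps$mean, x$null_overlaps$sd, x$null_overlaps$max,
              x$M, if (x$replace) " with replacement" else ""))
  cat(sprintf("  p = %.3g\n", x$p_estimate))
  invisible(x)
}
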