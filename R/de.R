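#' Counts-per-million matrix
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @param prior pseudo-count added to counts before scaling (0 = plain cpm).
#' @return matrix of cpm values with the dimensions of `counts`.
#' @export
cpm_matrix <- function(counts, lib_sizes = colSums(counts), prior = 0) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts + prior, 2, lib_sizes, "/") * 1e6
}

#' Detection filter on counts per million
#'
#' Retains genes with at least `min_cpm` counts per million in at least
#' `min_samples` samples (both thresholds inclusive). Library sizes are taken
#' from the unfiltered matrix and are carried through as an attribute so that
#' downstream cpm values stay on the original scale.
#'
#' @inheritParams cpm_matrix
#' @param min_cpm cpm detection threshold (default 0.5).
#' @param min_samples minimum number of samples at or above `min_cpm`
#'   (default 5).
#' @return the filtered count matrix with attribute `lib_sizes`.
#' @export
cpm_filter <- function(counts, lib_sizes = colSums(counts),
                       min_cpm = 0.5, min_samples = 5) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  keep <- rowSums(cpm_matrix(counts, lib_sizes) >= min_cpm) >= min_samples
  if (!any(keep)) warning("no genes pass the cpm filter")
  out <- counts[keep, , drop = FALSE]
  attr(out, "lib_sizes") <- lib_sizes
  out
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors (reference sample chosen by the
#' upper-quartile rule; M and A values doubly trimmed). Factors are scaled to
#' have geometric mean one. Computed with edgeR's TMM implementation.
#'
#' @inheritParams cpm_matrix
#' @param logratio_trim two-sided trim fraction on M values (default 0.30).
#' @param sum_trim two-sided trim fraction on A values (default 0.05).
#' @return numeric vector of per-sample normalization factors.
#' @export
tmm_normalize <- function(counts, lib_sizes = colSums(counts),
                          logratio_trim = 0.3, sum_trim = 0.05) {
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  f <- edgeR::calcNormFactors(counts, lib.size = lib_sizes, method = "TMM",
                              logratioTrim = logratio_trim, sumTrim = sum_trim)
  as.numeric(f)
}

## ---- internal NB machinery -------------------------------------------------

## Newton fit of a common (cpm-scale) mean per gene under NB(mu = m * N_j,
## size = 1/phi) with log link; U and J are score and information in beta =
## log m. Vectorized over genes.
.nb_fit_mean <- function(y, N, phi, iter = 60, tol = 1e-10) {
  G <- nrow(y)
  tot <- rowSums(y)
  m <- tot / sum(N)
  zero <- tot == 0
  if (all(zero)) return(m)
  Nm <- matrix(N, G, length(N), byrow = TRUE)
  for (i in seq_len(iter)) {
    mu <- m * Nm
    den <- 1 + phi * mu
    U <- rowSums((y - mu) / den)
    J <- rowSums(mu / den)
    step <- ifelse(zero, 0, U / pmax(J, 1e-300))
    step <- pmin(pmax(step, -5), 5)
    m <- m * exp(step)
    if (max(abs(step)) < tol) break
  }
  m[zero] <- 0
  m
}

.nb_loglik <- function(y, N, m, phi) {
  mu <- m * matrix(N, nrow(y), length(N), byrow = TRUE)
  rowSums(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

## Cox-Reid adjusted profile log-likelihood on a dispersion grid, with group
## means fitted once at a pilot dispersion (the profile in phi is flat in the
## means near their optimum, so the plug-in profile is adequate). Returns the
## G x K matrix of adjusted log-likelihoods.
.nb_apl_grid <- function(y, N, groups, grid, pilot_phi = 0.1) {
  G <- nrow(y)
  mus <- lapply(groups, function(idx) {
    m <- .nb_fit_mean(y[, idx, drop = FALSE], N[idx], rep_len(pilot_phi, G))
    m * matrix(N[idx], G, length(idx), byrow = TRUE)
  })
  ll <- matrix(0, G, length(grid))
  for (k in seq_along(grid)) {
    phi <- grid[k]
    acc <- numeric(G)
    for (gi in seq_along(groups)) {
      mu <- mus[[gi]]
      acc <- acc +
        rowSums(dnbinom(y[, groups[[gi]], drop = FALSE], size = 1 / phi,
                        mu = mu, log = TRUE)) -
        0.5 * log(pmax(rowSums(mu / (1 + phi * mu)), 1e-10))
    }
    ll[, k] <- acc
  }
  ll
}

## column-wise running mean over a window of w rows (rows assumed pre-sorted)
.run_mean <- function(x, w) {
  n <- nrow(x)
  w <- min(w, n)
  h <- w %/% 2
  cs <- apply(x, 2, cumsum)
  cs <- rbind(0, cs)
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

## argmax on a log-spaced grid with quadratic interpolation
.grid_argmax <- function(obj, lgrid) {
  k <- max.col(obj, ties.method = "first")
  K <- length(lgrid)
  step <- lgrid[2] - lgrid[1]
  out <- lgrid[k]
  inner <- which(k > 1 & k < K)
  if (length(inner)) {
    i <- inner
    ym <- obj[cbind(i, k[i] - 1)]
    y0 <- obj[cbind(i, k[i])]
    yp <- obj[cbind(i, k[i] + 1)]
    den <- ym - 2 * y0 + yp
    adj <- ifelse(den < 0, 0.5 * step * (ym - yp) / den, 0)
    out[i] <- lgrid[k[i]] + pmin(pmax(adj, -step), step)
  }
  exp(out)
}

#' Estimate per-gene NB dispersions with trend shrinkage
#'
#' Maximizes the Cox-Reid adjusted profile likelihood on a log-spaced
#' dispersion grid, forms a mean-expression trend by averaging adjusted
#' profile likelihoods over neighboring genes (genes ordered by average log
#' cpm), and shrinks each gene's estimate toward the trend by maximizing the
#' per-gene likelihood plus `prior_df / residual df` times the neighbor
#' average.
#'
#' @param counts filtered gene x sample integer count matrix.
#' @param group two-level factor giving the contrast groups.
#' @param eff_lib effective library sizes (library size times normalization
#'   factor).
#' @param grid dispersion grid (log-spaced).
#' @param prior_df prior degrees of freedom controlling shrinkage strength.
#' @param trend_span fraction of genes in the trend window.
#' @return list with `tagwise` and `trend` dispersion vectors.
#' @export
estimate_dispersion <- function(counts, group, eff_lib,
                                grid = exp(seq(log(1e-4), log(10),
                                               length.out = 16)),
                                prior_df = 10, trend_span = 0.25) {
  group <- as.factor(group)
  groups <- split(seq_along(group), group)
  N <- eff_lib / 1e6
  G <- nrow(counts)
  A <- log2(rowMeans(cpm_matrix(counts, eff_lib)) + 0.125)
  ord <- order(A)
  w <- max(50, ceiling(trend_span * G))
  df_resid <- max(1, length(group) - length(groups))
  prior_n <- prior_df / df_resid
  est <- .dispersion_from_groups(counts, N, groups, grid, prior_n, ord, w)
  c(est, list(ave_log_cpm = A))
}

## shared core for observed and permuted groupings: APL grid, neighbor
## averaging over the mean-expression ordering, and weighted-likelihood
## shrinkage toward the neighborhood (trend)
.dispersion_from_groups <- function(counts, N, groups, grid, prior_n,
                                    ord, w) {
  apl <- .nb_apl_grid(counts, N, groups, grid)
  apl_tr <- apl
  apl_tr[ord, ] <- .run_mean(apl[ord, , drop = FALSE], w)
  lgrid <- log(grid)
  list(tagwise = .grid_argmax(apl + prior_n * apl_tr, lgrid),
       trend = .grid_argmax(apl_tr, lgrid))
}

#' Negative-binomial likelihood-ratio test for a two-group contrast
#'
#' Fits per-gene NB means per group (log link, offsets from effective library
#' sizes) at a fixed per-gene dispersion and tests equality of means with a
#' likelihood-ratio test against the chi-square(1) reference. Dispersions are
#' estimated with [estimate_dispersion()] unless supplied.
#'
#' The reported `log2_fold_change` is the second group level versus the
#' first, lightly moderated with a 0.5-cpm prior on each group mean so that
#' empty groups stay finite; genes that are all zero get `p_raw = 1` and a
#' fold change of 0.
#'
#' @param counts filtered gene x sample integer count matrix.
#' @param group two-level factor; the contrast is `levels(group)[2]` versus
#'   `levels(group)[1]` (control first, experimental second).
#' @param lib_sizes per-sample library sizes.
#' @param norm_factors per-sample normalization factors (default 1).
#' @param dispersion optional per-gene dispersion vector; estimated if NULL.
#' @param prior_df shrinkage prior df passed to [estimate_dispersion()].
#' @return data.frame with columns `gene_id`, `log2_fold_change`, `p_raw`,
#'   `mean_cpm`, and attributes `dispersion` and `group`.
#' @export
nb_test <- function(counts, group, lib_sizes = colSums(counts),
                    norm_factors = rep(1, ncol(counts)),
                    dispersion = NULL, prior_df = 10) {
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(table(group) < 2)) stop("both groups need at least two samples")
  eff <- lib_sizes * norm_factors
  N <- eff / 1e6
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(counts, group, eff,
                                      prior_df = prior_df)$tagwise
  }
  ga <- which(group == levels(group)[1])
  gb <- which(group == levels(group)[2])
  mA <- .nb_fit_mean(counts[, ga, drop = FALSE], N[ga], dispersion)
  mB <- .nb_fit_mean(counts[, gb, drop = FALSE], N[gb], dispersion)
  m0 <- .nb_fit_mean(counts, N, dispersion)
  ll_alt <- .nb_loglik(counts[, ga, drop = FALSE], N[ga], mA, dispersion) +
    .nb_loglik(counts[, gb, drop = FALSE], N[gb], mB, dispersion)
  ll_null <- .nb_loglik(counts, N, m0, dispersion)
  lr <- pmax(2 * (ll_alt - ll_null), 0)
  p <- pchisq(lr, df = 1, lower.tail = FALSE)
  zero <- rowSums(counts) == 0
  p[zero] <- 1
  lfc <- log2((mB + 0.5) / (mA + 0.5))
  lfc[zero] <- 0
  res <- data.frame(
    gene_id = if (is.null(rownames(counts))) {
      sprintf("g%05d", seq_len(nrow(counts)))
    } else rownames(counts),
    log2_fold_change = lfc,
    p_raw = p,
    mean_cpm = rowMeans(cpm_matrix(counts, eff)),
    stringsAsFactors = FALSE
  )
  attr(res, "dispersion") <- dispersion
  attr(res, "group") <- group
  res
}

## enumerate or sample group-label assignments; returns a list of index
## vectors giving the samples assigned to the first group level. The observed
## assignment and (for equal group sizes) its label-swapped mirror are
## excluded: they would re-inject every observed p-value into the null and
## put a floor of 1/n_perm under the FDR of even a perfectly separated gene.
.permutation_splits <- function(group, n_perm, seed = NULL) {
  group <- as.factor(group)
  n <- length(group)
  obs <- which(group == levels(group)[1])
  n1 <- length(obs)
  total <- choose(n, n1)
  if (total <= n_perm) {
    splits <- utils::combn(n, n1, simplify = FALSE)
    obs2 <- sort(setdiff(seq_len(n), obs))
    splits <- Filter(function(s) !identical(s, obs) &&
                       !(n1 * 2 == n && identical(s, obs2)), splits)
  } else {
    if (!is.null(seed)) set.seed(seed)
    splits <- replicate(n_perm, sort(sample.int(n, n1)), simplify = FALSE)
    splits <- Filter(function(s) !identical(s, obs), splits)
  }
  splits
}

## plug-in pooled permutation FDR given observed p and a vector of null
## p-values from n_eff permutations, monotonized by step-up over the
## (p, |lfc| desc, gene_id) ordering
.empirical_fdr_from_null <- function(p_obs, p_null, n_eff,
                                     lfc = rep(0, length(p_obs)),
                                     gene_id = as.character(seq_along(p_obs))) {
  ns <- sort(p_null)
  V <- findInterval(p_obs, ns) / n_eff      # mean null count <= p
  R <- rank(p_obs, ties.method = "max")     # observed count <= p
  fdr <- pmin(1, pmax(V, 0) / pmax(R, 1))
  ord <- order(p_obs, -abs(lfc), gene_id)
  fdr[ord] <- rev(cummin(rev(fdr[ord])))
  fdr
}

#' Empirical FDR from sample-label permutations
#'
#' Builds a pooled null distribution of p-values by re-running the full NB
#' likelihood-ratio test — including per-gene dispersion re-estimation — under
#' permuted group labels, then estimates, for each observed
#' p-value threshold t, FDR(t) as the permutation-average count of null p <= t
#' divided by the observed count of p <= t, clipped to [0, 1] and monotonized
#' by step-up over the sorted observed p-values. When fewer distinct
#' label assignments exist than `n_perm`, all distinct splits are enumerated
#' and the effective count recorded; the observed assignment and its
#' label-swapped mirror are excluded from the null (n = 5 vs 5 gives 250
#' informative splits), so a gene whose observed p is never reached by any
#' permutation attains an empirical FDR of exactly 0.
#'
#' @param deg result of [nb_test()] for the same contrast.
#' @inheritParams nb_test
#' @param n_perm number of label permutations (default 500).
#' @param seed RNG seed used when permutations are sampled rather than
#'   enumerated.
#' @return `deg` with an `fdr_empirical` column added and attribute
#'   `n_perm_effective`.
#' @export
empirical_fdr <- function(deg, counts, group, lib_sizes = colSums(counts),
                          norm_factors = rep(1, ncol(counts)),
                          n_perm = 500, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  group <- as.factor(group)
  N <- lib_sizes * norm_factors / 1e6
  eff <- lib_sizes * norm_factors
  n <- ncol(counts)
  G <- nrow(counts)
  splits <- .permutation_splits(group, n_perm, seed)
  n_eff <- length(splits)
  grid <- exp(seq(log(1e-4), log(10), length.out = 16))
  A <- log2(rowMeans(cpm_matrix(counts, eff)) + 0.125)
  ord <- order(A)
  w <- max(50, ceiling(0.25 * G))
  prior_n <- 10 / max(1, n - 2)
  zero <- rowSums(counts) == 0
  p_null <- matrix(1, G, n_eff)
  for (b in seq_len(n_eff)) {
    ga <- splits[[b]]
    gb <- setdiff(seq_len(n), ga)
    phi <- .dispersion_from_groups(counts, N, list(ga, gb), grid, prior_n,
                                   ord, w)$tagwise
    mA <- .nb_fit_mean(counts[, ga, drop = FALSE], N[ga], phi)
    mB <- .nb_fit_mean(counts[, gb, drop = FALSE], N[gb], phi)
    m0 <- .nb_fit_mean(counts, N, phi)
    ll_alt <- .nb_loglik(counts[, ga, drop = FALSE], N[ga], mA, phi) +
      .nb_loglik(counts[, gb, drop = FALSE], N[gb], mB, phi)
    ll_null <- .nb_loglik(counts, N, m0, phi)
    pb <- pchisq(pmax(2 * (ll_alt - ll_null), 0), df = 1, lower.tail = FALSE)
    pb[zero] <- 1
    p_null[, b] <- pb
  }
  deg$fdr_empirical <- .empirical_fdr_from_null(
    deg$p_raw, as.vector(p_null), n_eff,
    lfc = deg$log2_fold_change, gene_id = deg$gene_id
  )
  attr(deg, "n_perm_effective") <- n_eff
  deg
}

#' Samples and group factor for a stage-versus-control contrast
#'
#' Selects, within one brain region, the experimental samples of a stage and
#' the control samples of that stage's circadian batch, and returns the
#' sample ids with a control-first group factor.
#'
#' @param design design data.frame with columns `sample_id`, `stage`, `arm`,
#'   `region`, `circadian_batch`.
#' @param region region label.
#' @param stage experimental stage label.
#' @return list with `sample_id` and `group` (levels control, experimental).
#' @export
stage_contrast <- function(design, region, stage) {
  d <- design[design$region == region, , drop = FALSE]
  batch <- unique(d$circadian_batch[d$stage == stage & d$arm == "experimental"])
  if (length(batch) != 1) stop("stage must map to exactly one circadian batch")
  keep <- (d$stage == stage & d$arm == "experimental") |
    (d$arm == "control" & d$circadian_batch == batch)
  d <- d[keep, , drop = FALSE]
  list(sample_id = d$sample_id,
       group = factor(d$arm, levels = c("control", "experimental")))
}

#' Run the per-region stage-wise differential expression analysis
#'
#' Applies the cpm detection filter and TMM normalization once per region,
#' then runs the NB likelihood-ratio test and permutation empirical FDR for
#' each experimental stage against its circadian-matched control group.
#'
#' @param counts gene x sample integer count matrix for one region.
#' @param design design data.frame (see [stage_contrast()]).
#' @param region region label to analyze.
#' @param stages ordered stage labels; defaults to the order of appearance of
#'   experimental stages in the design.
#' @param min_cpm,min_samples detection filter parameters.
#' @param n_perm permutations per contrast for the empirical FDR.
#' @param seed master seed; each contrast uses a derived substream.
#' @return named list (one DEG table per stage) with attribute `universe`
#'   (the post-filter gene ids).
#' @export
run_de <- function(counts, design, region, stages = NULL,
                   min_cpm = 0.5, min_samples = 5, n_perm = 500, seed = 1) {
  d <- design[design$region == region, , drop = FALSE]
  if (is.null(stages)) {
    stages <- unique(d$stage[d$arm == "experimental"])
  }
  counts <- counts[, d$sample_id, drop = FALSE]
  lib <- colSums(counts)
  filt <- cpm_filter(counts, lib, min_cpm = min_cpm, min_samples = min_samples)
  nf <- tmm_normalize(filt, lib)
  names(nf) <- colnames(filt)
  out <- vector("list", length(stages))
  names(out) <- stages
  for (i in seq_along(stages)) {
    ct <- stage_contrast(d, region, stages[i])
    y <- filt[, ct$sample_id, drop = FALSE]
    res <- nb_test(y, ct$group, lib_sizes = lib[ct$sample_id],
                   norm_factors = nf[ct$sample_id])
    res <- empirical_fdr(res, y, ct$group, lib_sizes = lib[ct$sample_id],
                         norm_factors = nf[ct$sample_id],
                         n_perm = n_perm, seed = derive_seed(seed, i))
    out[[i]] <- res
  }
  attr(out, "universe") <- rownames(filt)
  attr(out, "region") <- region
  out
}
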