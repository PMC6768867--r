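#' Standardized expression panel
#'
#' Builds the gene x sample panel that network inference operates on:
#' log2 cpm (0.5 pseudo-count) standardized per gene to mean 0, s.d. 1.
#' Constant genes cannot be standardized and are dropped with a message.
#'
#' @param counts gene x sample count matrix.
#' @param tf_ids gene ids designated as transcription factors.
#' @param lib_sizes library sizes for the cpm transform.
#' @param conditions optional per-sample condition labels.
#' @return object of class `expression_panel` with elements `z` (standardized
#'   matrix), `tf_ids`, `gene_ids`, `samples`, `conditions`.
#' @export
expression_panel <- function(counts, tf_ids, lib_sizes = colSums(counts),
                             conditions = NULL) {
  logcpm <- log2((counts + 0.5) / (lib_sizes + 1) * 1e6)
  sds <- apply(logcpm, 1, sd)
  keep <- sds > 1e-12
  if (!all(keep)) {
    message(sum(!keep), " constant gene(s) dropped from the panel")
  }
  z <- (logcpm[keep, , drop = FALSE] -
          rowMeans(logcpm[keep, , drop = FALSE])) / sds[keep]
  structure(list(z = z, tf_ids = intersect(tf_ids, rownames(z)),
                 gene_ids = rownames(z), samples = colnames(counts),
                 conditions = conditions),
            class = "expression_panel")
}

## equal-frequency bin labels from ranks (deterministic tie-break)
.rank_bins <- function(x, bins) {
  ceiling(rank(x, ties.method = "first") * bins / length(x))
}

#' Default number of MI bins
#' @param n number of samples.
#' @return `ceiling(sqrt(n / 5))`, at least 2.
#' @export
mi_bins_default <- function(n) max(2L, as.integer(ceiling(sqrt(n / 5))))

#' Rank-binned mutual information
#'
#' Plug-in mutual information (nats) between two expression profiles after
#' equal-frequency (rank) binning, invariant to strictly monotone transforms
#' of either profile.
#'
#' @param x,y numeric profiles of equal length (>= 8), non-constant.
#' @param bins number of equal-frequency bins (default [mi_bins_default()]).
#' @return MI in nats (non-negative).
#' @export
mutual_information <- function(x, y, bins = NULL) {
  n <- length(x)
  if (length(y) != n || n < 8) stop("profiles must have equal length >= 8")
  if (sd(x) < 1e-12 || sd(y) < 1e-12) stop("constant profile")
  if (is.null(bins)) bins <- mi_bins_default(n)
  bx <- .rank_bins(x, bins)
  by <- .rank_bins(y, bins)
  joint <- tabulate((bx - 1L) * bins + by, nbins = bins * bins) / n
  px <- tabulate(bx, bins) / n
  py <- tabulate(by, bins) / n
  pij <- joint[joint > 0]
  outer_p <- as.vector(outer(py, px))[joint > 0]
  max(0, sum(pij * log(pij / outer_p)))
}

#' Analytic significance of a rank-binned MI value
#'
#' Under independence, twice the sample size times the plug-in MI (the
#' G-statistic of the binned contingency table) is asymptotically chi-square
#' with (bins - 1)^2 degrees of freedom. The Williams correction for equal
#' margins (`q = 1 + (bins + 1)^2 / (6 n)`) is applied, which matches the
#' permutation null mean closely at the sample sizes used here.
#'
#' @param mi MI in nats.
#' @param n_samples number of samples.
#' @param bins number of bins used.
#' @return p-value.
#' @export
mi_significance <- function(mi, n_samples, bins) {
  q <- 1 + (bins + 1)^2 / (6 * n_samples)
  pchisq(2 * n_samples * mi / q, df = (bins - 1)^2, lower.tail = FALSE)
}

#' Fit the TF-target regulatory network
#'
#' For each non-TF gene: candidate regulators are the TFs sharing
#' significant mutual information with the target (MI p below `mi_alpha`); a
#' sparse linear model is then built on the standardized profiles by forward
#' selection with a BIC stop, and the target's edges are retained only when
#' the final model's root-mean-square deviation is below `rmsd_max` (on the
#' standardized scale, so 0.33 means a prediction error under one-third of
#' the target's s.d.). Targets with no MI-significant TF are excluded and
#' counted.
#'
#' @param panel an [expression_panel()].
#' @param mi_alpha MI significance threshold (default 1e-6).
#' @param rmsd_max RMSD retention threshold (default 0.33).
#' @param bins MI bins (default [mi_bins_default()]).
#' @param max_regulators cap on regulators per target.
#' @return object of class `trn_model` with `edges` (tf, target, mi, mi_p,
#'   rmsd, coefficient, sign), `tf_target_counts`, and `n_excluded`.
#' @export
fit_targets <- function(panel, mi_alpha = 1e-6, rmsd_max = 0.33,
                        bins = NULL, max_regulators = 5) {
  stopifnot(inherits(panel, "expression_panel"))
  z <- panel$z
  n <- ncol(z)
  if (is.null(bins)) bins <- mi_bins_default(n)
  tfs <- panel$tf_ids
  if (!length(tfs)) stop("panel has no TFs")
  targets <- setdiff(rownames(z), tfs)
  binned <- t(apply(z, 1, .rank_bins, bins = bins))

  mi_pair <- function(bt, bg) {
    joint <- tabulate((bt - 1L) * bins + bg, nbins = bins * bins) / n
    px <- tabulate(bt, bins) / n
    py <- tabulate(bg, bins) / n
    pij <- joint[joint > 0]
    op <- as.vector(outer(py, px))[joint > 0]
    max(0, sum(pij * log(pij / op)))
  }

  edges <- list()
  n_excluded <- 0L
  for (g in targets) {
    mi <- vapply(tfs, function(tf) mi_pair(binned[tf, ], binned[g, ]), 0)
    mip <- mi_significance(mi, n, bins)
    cand <- tfs[mip < mi_alpha]
    if (!length(cand)) {
      n_excluded <- n_excluded + 1L
      next
    }
    y <- z[g, ]
    sel <- character(0)
    rss <- sum(y^2)
    bic <- n * log(rss / n)
    pool <- cand
    while (length(pool) && length(sel) < max_regulators) {
      trial <- vapply(pool, function(tf) {
        X <- t(z[c(sel, tf), , drop = FALSE])
        sum(lsfit(X, y, intercept = FALSE)$residuals^2)
      }, 0)
      best <- which.min(trial)
      new_bic <- n * log(max(trial[best], 1e-12) / n) +
        (length(sel) + 1) * log(n)
      if (new_bic >= bic) break
      sel <- c(sel, pool[best])
      pool <- pool[-best]
      bic <- new_bic
    }
    if (!length(sel)) {
      n_excluded <- n_excluded + 1L
      next
    }
    X <- t(z[sel, , drop = FALSE])
    fit <- lsfit(X, y, intercept = FALSE)
    rmsd <- sqrt(mean(fit$residuals^2))
    if (rmsd < rmsd_max) {
      edges[[length(edges) + 1]] <- data.frame(
        tf = sel, target = g, mi = mi[sel], mi_p = mip[sel], rmsd = rmsd,
        coefficient = unname(fit$coefficients),
        sign = sign(unname(fit$coefficients)),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(tf = character(), target = character(), mi = numeric(),
               mi_p = numeric(), rmsd = numeric(), coefficient = numeric(),
               sign = numeric())
  structure(list(edges = edges,
                 tf_target_counts = table(factor(edges$tf, levels = tfs)),
                 n_excluded = n_excluded,
                 params = list(mi_alpha = mi_alpha, rmsd_max = rmsd_max,
                               bins = bins)),
            class = "trn_model")
}

#' TF target enrichment in DEG sets
#'
#' Upper-tail hypergeometric test of each TF's target set against each
#' experiment's pooled DEG set over a common gene universe, Bonferroni
#' corrected across the TFs tested. TFs with no targets are skipped.
#'
#' @param model a [fit_targets()] result.
#' @param deg_sets named list of DEG gene sets (one per experiment).
#' @param universe gene universe the sets live in.
#' @param alpha significance level on the corrected p (default 0.05).
#' @return data.frame tf x set with overlap, p, Bonferroni p and enrichment
#'   flag.
#' @export
tf_enrichment <- function(model, deg_sets, universe, alpha = 0.05) {
  stopifnot(inherits(model, "trn_model"))
  for (s in deg_sets) {
    if (!all(s %in% universe)) stop("deg sets must be subsets of the universe")
  }
  targets_by_tf <- split(model$edges$target, model$edges$tf)
  targets_by_tf <- Filter(length, targets_by_tf)
  if (!length(targets_by_tf)) stop("model has no TF with targets")
  n_tf <- length(targets_by_tf)
  N <- length(universe)
  rows <- list()
  for (tf in names(targets_by_tf)) {
    tg <- intersect(targets_by_tf[[tf]], universe)
    for (set_name in names(deg_sets)) {
      dg <- deg_sets[[set_name]]
      k <- length(intersect(tg, dg))
      p <- hyper_overlap_p(k, length(tg), length(dg), N)
      rows[[length(rows) + 1]] <- data.frame(
        tf = tf, set = set_name, n_targets = length(tg), n_deg = length(dg),
        overlap = k, p = p, p_bonferroni = min(1, p * n_tf),
        enriched = min(1, p * n_tf) < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cross-experiment direction table for enriched TFs
#'
#' For each TF, tabulates the direction of its own differential expression
#' (up / down / ns at `fdr`) in every condition of two experiments, and flags
#' TFs regulated in opposite directions: significantly up in some condition
#' of one experiment and significantly down in some condition of the other.
#'
#' @param tf_ids TFs to report.
#' @param experiments named list of two experiments, each a named list of
#'   DEG tables (condition -> table).
#' @param fdr significance threshold on the empirical FDR (default 0.01).
#' @return list with `table` (long data.frame tf, experiment, condition,
#'   direction) and `opposite` (named logical flag per TF).
#' @export
opposite_direction_report <- function(tf_ids, experiments, fdr = 0.01) {
  if (length(experiments) != 2) stop("exactly two experiments expected")
  rows <- list()
  for (exp_name in names(experiments)) {
    for (cond in names(experiments[[exp_name]])) {
      tab <- experiments[[exp_name]][[cond]]
      i <- match(tf_ids, tab$gene_id)
      dir <- rep("ns", length(tf_ids))
      hit <- !is.na(i) & tab$fdr_empirical[i] < fdr
      dir[hit] <- ifelse(tab$log2_fold_change[i[hit]] > 0, "up", "down")
      rows[[length(rows) + 1]] <- data.frame(
        tf = tf_ids, experiment = exp_name, condition = cond, direction = dir,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  exps <- names(experiments)
  opposite <- vapply(tf_ids, function(tf) {
    d1 <- tab$direction[tab$tf == tf & tab$experiment == exps[1]]
    d2 <- tab$direction[tab$tf == tf & tab$experiment == exps[2]]
    ("up" %in% d1 && "down" %in% d2) || ("down" %in% d1 && "up" %in% d2)
  }, TRUE)
  list(table = tab, opposite = opposite)
}
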