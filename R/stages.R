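#' Bundle per-stage DEG tables into an ordered stage series
#'
#' @param tables named list of DEG tables (output of [nb_test()] +
#'   [empirical_fdr()]), one per stage, in stage order or named by stage.
#' @param stages ordered stage labels (defaults to `names(tables)`).
#' @param region region label carried along for reporting.
#' @return object of class `stage_series` with the shared gene universe.
#' @export
stage_series <- function(tables, stages = names(tables), region = NA) {
  if (length(stages) < 2) stop("a stage series needs at least two stages")
  tables <- tables[stages]
  ids <- lapply(tables, function(t) sort(t$gene_id))
  if (!all(vapply(ids[-1], identical, TRUE, ids[[1]]))) {
    stop("all stage tables must share one gene universe")
  }
  universe <- tables[[1]]$gene_id
  fdr <- vapply(tables, function(t) t$fdr_empirical[match(universe, t$gene_id)],
                numeric(length(universe)))
  lfc <- vapply(tables,
                function(t) t$log2_fold_change[match(universe, t$gene_id)],
                numeric(length(universe)))
  rownames(fdr) <- rownames(lfc) <- universe
  structure(list(tables = tables, stages = stages, region = region,
                 universe = universe, fdr = fdr, lfc = lfc),
            class = "stage_series")
}

#' Stage-unique genes under a relaxed exclusion schedule
#'
#' A gene is unique to a focal stage when its empirical FDR is below
#' `focal_fdr` there and at or above the relaxation threshold at every other
#' stage. To guard against false negatives at the other stages (genes that
#' barely miss significance elsewhere), the exclusion threshold is relaxed
#' well above `focal_fdr`: the terminal (most relaxed) schedule value defines
#' the reported unique sets, and the sets at every schedule point are kept
#' for sensitivity sweeps.
#'
#' @param series a [stage_series()].
#' @param focal_fdr significance cutoff at the focal stage (default 0.01).
#' @param relaxed_schedule increasing thresholds applied to the non-focal
#'   stages; all must exceed `focal_fdr`.
#' @return list with `sets` (per-stage unique gene vectors at the terminal
#'   relaxation), `schedule_sets` (per relaxation value), and `exclusions`
#'   (focal-significant genes dropped, with the stage responsible).
#' @export
unique_genes <- function(series, focal_fdr = 0.01,
                         relaxed_schedule = c(0.05, 0.10, 0.20)) {
  stopifnot(inherits(series, "stage_series"))
  if (any(relaxed_schedule <= focal_fdr)) {
    stop("relaxed_schedule values must exceed focal_fdr")
  }
  relaxed_schedule <- sort(relaxed_schedule)
  F <- series$fdr
  S <- length(series$stages)
  schedule_sets <- lapply(relaxed_schedule, function(r) {
    sets <- lapply(seq_len(S), function(s) {
      ok <- F[, s] < focal_fdr &
        rowSums(F[, -s, drop = FALSE] < r) == 0
      rownames(F)[ok]
    })
    names(sets) <- series$stages
    sets
  })
  names(schedule_sets) <- as.character(relaxed_schedule)
  terminal <- relaxed_schedule[length(relaxed_schedule)]
  sets <- schedule_sets[[length(schedule_sets)]]
  excl <- list()
  for (s in seq_len(S)) {
    focal_sig <- rownames(F)[F[, s] < focal_fdr]
    dropped <- setdiff(focal_sig, sets[[s]])
    if (length(dropped)) {
      other <- F[dropped, -s, drop = FALSE]
      by_stage <- series$stages[-s][apply(other, 1, which.min)]
      excl[[length(excl) + 1]] <- data.frame(
        gene_id = dropped, focal_stage = series$stages[s],
        excluded_by_stage = by_stage, stringsAsFactors = FALSE)
    }
  }
  list(sets = sets, schedule_sets = schedule_sets,
       focal_fdr = focal_fdr, relaxed_schedule = relaxed_schedule,
       terminal = terminal,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(gene_id = character(), focal_stage = character(),
                    excluded_by_stage = character()))
}

#' Upper-tail hypergeometric overlap p-value
#'
#' P(X >= k) for the overlap of two sets of sizes `n_a`, `n_b` drawn from a
#' universe of size `n_universe`.
#'
#' @param k observed overlap.
#' @param n_a,n_b set sizes.
#' @param n_universe universe size.
#' @return p-value.
#' @export
hyper_overlap_p <- function(k, n_a, n_b, n_universe) {
  if (n_a > n_universe || n_b > n_universe) {
    stop("set larger than universe")
  }
  phyper(k - 1, n_a, n_universe - n_a, n_b, lower.tail = FALSE)
}

#' Pairwise overlap of stage DEG sets
#'
#' Hypergeometric upper-tail test of every stage pair's DEG overlap over the
#' region's post-filter gene universe, BH-adjusted across pairs.
#'
#' @param series a [stage_series()].
#' @param deg_fdr DEG significance cutoff (default 0.01).
#' @return data.frame with one row per unordered stage pair: overlap, set
#'   sizes, universe size, hypergeometric p and BH FDR.
#' @export
pairwise_overlap <- function(series, deg_fdr = 0.01) {
  stopifnot(inherits(series, "stage_series"))
  F <- series$fdr
  sets <- lapply(seq_along(series$stages),
                 function(s) rownames(F)[F[, s] < deg_fdr])
  N <- length(series$universe)
  pairs <- utils::combn(length(series$stages), 2)
  out <- data.frame(
    stage_a = series$stages[pairs[1, ]],
    stage_b = series$stages[pairs[2, ]],
    overlap = apply(pairs, 2, function(ij)
      length(intersect(sets[[ij[1]]], sets[[ij[2]]]))),
    size_a = lengths(sets)[pairs[1, ]],
    size_b = lengths(sets)[pairs[2, ]],
    universe = N, stringsAsFactors = FALSE)
  out$p <- mapply(hyper_overlap_p, out$overlap, out$size_a, out$size_b, N)
  out$fdr <- p.adjust(out$p, method = "BH")
  out
}

#' Added shared genes along the stage series
#'
#' For each focal stage, the genes that first become differentially expressed
#' there (significant at the focal stage, not significant at any preceding
#' stage) and stay differentially expressed at one or more later stages (not
#' necessarily the immediate successor). Later-stage significance only counts
#' toward membership through stage pairs whose DEG overlap passes the
#' hypergeometric pre-screen. The final stage has no subsequent stage and
#' yields an empty set by definition. Direction vectors record the
#' log2-fold-change sign at the focal stage and at every later stage where
#' the gene is significant.
#'
#' @param series a [stage_series()].
#' @param deg_fdr DEG significance cutoff (default 0.01).
#' @param overlap_prescreen_fdr stage-pair overlap FDR below which a pair may
#'   contribute (default 0.05).
#' @param overlap optional precomputed [pairwise_overlap()] result.
#' @return object of class `added_shared`: per focal stage a data.frame with
#'   gene_id, the per-stage sign pattern (`+`/`-` where significant, `.`
#'   elsewhere), the number of significant stages `k` from the focal stage
#'   on, and concordance flags.
#' @export
added_shared <- function(series, deg_fdr = 0.01,
                         overlap_prescreen_fdr = 0.05, overlap = NULL) {
  stopifnot(inherits(series, "stage_series"))
  if (is.null(overlap)) overlap <- pairwise_overlap(series, deg_fdr)
  S <- length(series$stages)
  sig <- series$fdr < deg_fdr
  sgn <- sign(series$lfc)
  pass <- matrix(FALSE, S, S)
  for (i in seq_len(nrow(overlap))) {
    a <- match(overlap$stage_a[i], series$stages)
    b <- match(overlap$stage_b[i], series$stages)
    pass[a, b] <- pass[b, a] <- overlap$fdr[i] < overlap_prescreen_fdr
  }
  taken <- character(0)
  sets <- vector("list", S)
  names(sets) <- series$stages
  for (s in seq_len(S)) {
    if (s == S) {
      members <- character(0)
    } else {
      later <- seq(s + 1, S)
      contributes <- later[pass[s, later]]
      ok <- sig[, s]
      if (s > 1) ok <- ok & rowSums(sig[, seq_len(s - 1), drop = FALSE]) == 0
      ok <- ok & (if (length(contributes))
        rowSums(sig[, contributes, drop = FALSE]) > 0 else FALSE)
      members <- setdiff(rownames(sig)[ok], taken)
    }
    if (length(members)) {
      pat <- vapply(members, function(g) {
        ch <- rep(".", S)
        on <- which(sig[g, ])
        ch[on] <- ifelse(sgn[g, on] > 0, "+", "-")
        paste(ch, collapse = "")
      }, "")
      from_focal <- lapply(members, function(g) {
        on <- which(sig[g, ])
        on <- on[on >= s]
        sgn[g, on]
      })
      k <- lengths(from_focal)
      sets[[s]] <- data.frame(
        gene_id = members, focal_stage = series$stages[s], pattern = pat,
        k = k,
        all_up = vapply(from_focal, function(v) all(v > 0), TRUE),
        all_down = vapply(from_focal, function(v) all(v < 0), TRUE),
        stringsAsFactors = FALSE, row.names = NULL)
    } else {
      sets[[s]] <- data.frame(gene_id = character(), focal_stage = character(),
                              pattern = character(), k = integer(),
                              all_up = logical(), all_down = logical())
    }
    taken <- c(taken, members)
  }
  structure(list(sets = sets, stages = series$stages, deg_fdr = deg_fdr,
                 overlap_prescreen_fdr = overlap_prescreen_fdr,
                 overlap = overlap, region = series$region),
            class = "added_shared")
}

## chi-square of observed vs chance-expected concordance for genes with k
## significant stages each: P(all up) = P(all down) = (1/2)^k per gene
.concordance_stats <- function(k, all_up, all_down) {
  if (any(k < 2)) stop("concordance needs at least two significant stages per gene")
  n <- length(k)
  e_dir <- sum(0.5^k)
  obs <- c(up = sum(all_up), down = sum(all_down),
           discordant = sum(!all_up & !all_down))
  expd <- c(up = e_dir, down = e_dir, discordant = n - 2 * e_dir)
  chi <- sum((obs - expd)^2 / expd)
  list(n = n, observed = obs, expected = expd, concordant = sum(obs[1:2]),
       expected_concordant = 2 * e_dir, chi_square = chi, chi_df = 2,
       p = pchisq(chi, df = 2, lower.tail = FALSE))
}

#' Direction concordance of added shared genes
#'
#' A member gene significant in k stages (its focal stage plus k - 1 later
#' stages) is concordant when all k log-fold-change signs agree; under the
#' chance null each direction has probability (1/2)^k per gene. Compares
#' observed (concordant-up, concordant-down, discordant) counts with their
#' chance expectations by chi-square on the three categories (df = 2), per
#' focal set and pooled across sets.
#'
#' @param asr an [added_shared()] result.
#' @return list with `per_set` (data.frame of per-focal-stage statistics) and
#'   `pooled` (the same statistics over all member genes).
#' @export
concordance_test <- function(asr) {
  stopifnot(inherits(asr, "added_shared"))
  nonempty <- Filter(nrow, asr$sets)
  if (!length(nonempty)) stop("no added shared genes to test")
  per <- lapply(nonempty, function(d)
    .concordance_stats(d$k, d$all_up, d$all_down))
  per_set <- data.frame(
    focal_stage = names(nonempty),
    n = vapply(per, `[[`, 0, "n"),
    concordant = vapply(per, `[[`, 0, "concordant"),
    expected_concordant = vapply(per, `[[`, 0, "expected_concordant"),
    chi_square = vapply(per, `[[`, 0, "chi_square"),
    chi_df = 2,
    p = vapply(per, `[[`, 0, "p"),
    row.names = NULL, stringsAsFactors = FALSE)
  all_members <- do.call(rbind, nonempty)
  pooled <- .concordance_stats(all_members$k, all_members$all_up,
                               all_members$all_down)
  list(per_set = per_set, pooled = pooled)
}

#' Signed z-scores from a DEG table
#'
#' Two-sided p-values are mapped to |z| via the normal quantile and signed by
#' the log2 fold change, for use in [directional_set_test()].
#'
#' @param deg a DEG table with `p_raw` and `log2_fold_change`.
#' @return named numeric vector of signed z-scores.
#' @export
deg_z <- function(deg) {
  p <- pmin(pmax(deg$p_raw, 1e-300), 1)
  z <- qnorm(p / 2, lower.tail = FALSE) * sign(deg$log2_fold_change)
  names(z) <- deg$gene_id
  z
}

#' Sign-flip directional gene-set test
#'
#' Self-contained set test of whether a gene set tends to be up- or
#' down-regulated in a target contrast: the observed mean signed z of the set
#' is compared to a null built by randomly flipping each member's sign
#' (exchangeability of the signed group-mean differences under the null of no
#' direction). One-sided p-value for the stated direction, bounded below by
#' 1/(n_rot + 1).
#'
#' @param z named signed z vector for the target contrast (see [deg_z()]).
#' @param gene_set member gene ids.
#' @param direction "Up" or "Down".
#' @param n_rot number of random sign assignments (default 9999).
#' @param seed RNG seed.
#' @return list with `p`, `statistic` (observed mean z), `direction`, `n_rot`.
#' @export
directional_set_test <- function(z, gene_set, direction = c("Up", "Down"),
                                 n_rot = 9999, seed = NULL) {
  direction <- match.arg(direction)
  if (length(gene_set) == 0) stop("empty gene set")
  zs <- z[gene_set]
  if (anyNA(zs)) stop("gene set members missing from z")
  if (!is.null(seed)) set.seed(seed)
  m <- length(zs)
  obs <- mean(zs)
  flips <- matrix(sample(c(-1, 1), n_rot * m, replace = TRUE), n_rot, m)
  null_stat <- as.vector(flips %*% abs(zs)) / m
  extreme <- if (direction == "Up") sum(null_stat >= obs) else
    sum(null_stat <= obs)
  list(p = (1 + extreme) / (1 + n_rot), statistic = obs,
       direction = direction, n_rot = n_rot)
}
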