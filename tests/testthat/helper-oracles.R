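# Independent oracles and fixture builders used across the suite.

# Exhaustive hypergeometric upper tail: enumerate every possible draw of
# size b from a universe of size n_universe and count how often the overlap
# with the fixed set 1..a reaches k.
hyper_oracle <- function(k, a, b, n_universe) {
  A <- seq_len(a)
  draws <- utils::combn(n_universe, b, simplify = FALSE)
  mean(vapply(draws, function(B) length(intersect(A, B)) >= k, TRUE))
}

# Hand implementation of the doubly-trimmed weighted mean-of-M TMM factor
# (reference column by the upper-quartile rule, factors scaled to geometric
# mean one). Independent of edgeR.
tmm_oracle <- function(counts, lib = colSums(counts),
                       logratio_trim = 0.3, sum_trim = 0.05) {
  f75 <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(j) {
    obs <- counts[, j] / lib[j]
    rf <- counts[, ref] / lib[ref]
    fin <- obs > 0 & rf > 0
    logR <- log2(obs[fin] / rf[fin])
    absE <- (log2(obs[fin]) + log2(rf[fin])) / 2
    v <- (lib[j] - counts[fin, j]) / (lib[j] * counts[fin, j]) +
      (lib[ref] - counts[fin, ref]) / (lib[ref] * counts[fin, ref])
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1;      hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one, 0)
  f / exp(mean(log(f)))
}

# Brute-force rule evaluator for added shared genes on a significance grid:
# plain loops re-stating the membership rules (first significant at the
# focal stage, significant at a later stage reachable through the overlap
# pre-screen, not claimed by an earlier focal set).
added_shared_oracle <- function(sig, deg_fdr = 0.01, prescreen_fdr = 0.05) {
  S <- ncol(sig)
  N <- nrow(sig)
  sets <- lapply(seq_len(S), function(s) character(0))
  # pre-screen: BH-adjusted hypergeometric overlap across all stage pairs
  pairs <- utils::combn(S, 2)
  pvals <- apply(pairs, 2, function(ij) {
    A <- which(sig[, ij[1]]); B <- which(sig[, ij[2]])
    phyper(length(intersect(A, B)) - 1, length(A), N - length(A),
           length(B), lower.tail = FALSE)
  })
  fdrs <- p.adjust(pvals, "BH")
  pass <- matrix(FALSE, S, S)
  for (c in seq_len(ncol(pairs))) {
    pass[pairs[1, c], pairs[2, c]] <- fdrs[c] < prescreen_fdr
    pass[pairs[2, c], pairs[1, c]] <- fdrs[c] < prescreen_fdr
  }
  claimed <- character(0)
  for (s in seq_len(S - 1)) {
    for (g in rownames(sig)) {
      if (!sig[g, s]) next
      if (s > 1 && any(sig[g, 1:(s - 1)])) next
      later_ok <- FALSE
      for (t in (s + 1):S) {
        if (sig[g, t] && pass[s, t]) later_ok <- TRUE
      }
      if (!later_ok) next
      if (g %in% claimed) next
      sets[[s]] <- c(sets[[s]], g)
      claimed <- c(claimed, g)
    }
  }
  names(sets) <- colnames(sig)
  sets
}

# DEG-table fixture from a significance indicator and signs
make_deg_table <- function(universe, sig, sign = rep(1, length(universe)),
                           sig_fdr = 1e-4, ns_fdr = 0.6) {
  data.frame(gene_id = universe,
             log2_fold_change = sign * ifelse(sig, 2, 0.1),
             p_raw = ifelse(sig, 1e-6, 0.5),
             fdr_empirical = ifelse(sig, sig_fdr, ns_fdr),
             mean_cpm = 10, stringsAsFactors = FALSE)
}

# stage_series fixture from a logical significance grid (+ optional signs)
series_from_grid <- function(sig, signs = NULL, region = "toy") {
  if (is.null(signs)) signs <- matrix(1, nrow(sig), ncol(sig))
  tabs <- lapply(seq_len(ncol(sig)), function(s)
    make_deg_table(rownames(sig), sig[, s], signs[, s]))
  names(tabs) <- colnames(sig)
  stage_series(tabs, region = region)
}

# small two-group NB count fixture; planted effects alternate sign so the
# composition stays balanced and library sizes comparable
nb_toy <- function(G = 200, n = 5, mu_log = log(50), sd_log = 1,
                   phi = 0.1, lfc = 0, n_de = 0, seed = 1) {
  set.seed(seed)
  mu <- exp(rnorm(G, mu_log, sd_log))
  de <- seq_len(n_de)
  sgn <- rep_len(c(1, -1), n_de)
  y <- matrix(0L, G, 2 * n)
  for (j in seq_len(2 * n)) {
    m <- mu
    if (j > n && n_de > 0) m[de] <- m[de] * 2^(sgn * lfc)
    y[, j] <- rnbinom(G, mu = m, size = 1 / phi)
  }
  rownames(y) <- sprintf("g%04d", seq_len(G))
  colnames(y) <- sprintf("s%02d", seq_len(2 * n))
  list(counts = y, group = factor(rep(c("control", "experimental"),
                                      each = n),
                                  levels = c("control", "experimental")),
       de = rownames(y)[de], de_sign = sgn)
}
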