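test_that("mutual information is symmetric, maximal on self, and rank-invariant", {
  set.seed(41)
  x <- rnorm(60); y <- rnorm(60)
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  # self-MI equals the binned entropy of the profile (log B for equal bins)
  B <- mi_bins_default(60)
  self <- mutual_information(x, x, bins = B)
  px <- tabulate(ceiling(rank(x) * B / 60), B) / 60
  expect_equal(self, -sum(px * log(px)))
  # invariant to strictly monotone transforms
  expect_equal(mutual_information(x, y), mutual_information(exp(x), y^3 + 5 * y))
  expect_error(mutual_information(rep(1, 60), y), "constant")
  expect_error(mutual_information(x[1:5], y[1:5]), "length")
})

test_that("independent profiles stay below the extreme-MI cutoff at n = 60", {
  set.seed(42)
  B <- mi_bins_default(60)
  cutoff <- qchisq(1e-6, (B - 1)^2, lower.tail = FALSE) / (2 * 60)
  mis <- replicate(300, mutual_information(rnorm(60), rnorm(60)))
  expect_lt(mean(mis), cutoff)
  expect_equal(sum(mis >= cutoff), 0)
})

test_that("analytic MI significance agrees with its permutation oracle", {
  expect_equal(mi_significance(0, 60, 4), 1)
  expect_lt(mi_significance(0.5, 60, 4), mi_significance(0.3, 60, 4))
  # mid-range dependence: permutation p at 1e4 permutations vs chi-square
  set.seed(7)
  n <- 200
  x <- rnorm(n); y <- 0.28 * x + rnorm(n, 0, 1)
  B <- mi_bins_default(n)
  mi_obs <- mutual_information(x, y, B)
  p_ana <- mi_significance(mi_obs, n, B)
  perm <- replicate(1e4, mutual_information(x, sample(y), B))
  p_perm <- (1 + sum(perm >= mi_obs)) / (1 + 1e4)
  se <- sqrt(p_perm * (1 - p_perm) / 1e4)
  # the chi-square null is a large-sample approximation; require agreement
  # within Monte Carlo error plus a modest finite-sample allowance
  expect_lt(abs(p_ana - p_perm), 3 * se + 0.25 * max(p_perm, p_ana))
})

test_that("network fitting recovers exact and planted structure", {
  set.seed(17)
  n <- 60
  z_tf <- matrix(rnorm(3 * n), 3, n,
                 dimnames = list(c("tf1", "tf2", "tf3"), NULL))
  z_tf <- (z_tf - rowMeans(z_tf)) / apply(z_tf, 1, sd)
  tgt <- 0.8 * z_tf["tf1", ]
  tgt <- (tgt - mean(tgt)) / sd(tgt)
  z <- rbind(z_tf, t1 = tgt)
  colnames(z) <- paste0("s", seq_len(n))
  panel <- structure(list(z = z, tf_ids = c("tf1", "tf2", "tf3"),
                          gene_ids = rownames(z), samples = colnames(z)),
                     class = "expression_panel")
  fit <- fit_targets(panel)
  expect_equal(nrow(fit$edges), 1)
  expect_equal(fit$edges$tf, "tf1")
  expect_equal(fit$edges$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$edges$sign, 1)
  # retained edges always satisfy both thresholds
  expect_true(all(fit$edges$mi_p < fit$params$mi_alpha))
  expect_true(all(fit$edges$rmsd < fit$params$rmsd_max))
})

test_that("independent targets are excluded under the null", {
  set.seed(23)
  n <- 60
  z <- matrix(rnorm(103 * n), 103, n)
  z <- (z - rowMeans(z)) / apply(z, 1, sd)
  rownames(z) <- c(paste0("tf", 1:3), sprintf("g%03d", 1:100))
  panel <- structure(list(z = z, tf_ids = paste0("tf", 1:3),
                          gene_ids = rownames(z), samples = NULL),
                     class = "expression_panel")
  fit <- fit_targets(panel)
  expect_gte(fit$n_excluded, 99)      # exclusion rate > 99% under the null
})

test_that("TF enrichment matches exhaustive enumeration and edge cases", {
  # toy margins: universe 20, targets 6, DEGs 8, overlap 5
  universe <- sprintf("g%02d", 1:20)
  edges <- data.frame(tf = "tfA", target = universe[1:6], mi = 1,
                      mi_p = 1e-8, rmsd = 0.1, coefficient = 1, sign = 1)
  model <- structure(list(edges = edges, tf_target_counts = NULL,
                          n_excluded = 0,
                          params = list(mi_alpha = 1e-6, rmsd_max = 0.33)),
                     class = "trn_model")
  degs <- list(care = c(universe[1:5], universe[15:17]))   # overlap 5, |D|=8
  enr <- tf_enrichment(model, degs, universe)
  expect_equal(enr$overlap, 5)
  expect_equal(enr$p, hyper_oracle(5, 6, 8, 20))
  expect_equal(enr$p_bonferroni, min(1, enr$p * 1))
  # targets exactly equal to the DEG set: minimal p for those margins
  degs2 <- list(care = universe[1:6])
  enr2 <- tf_enrichment(model, degs2, universe)
  expect_equal(enr2$p, min(vapply(0:6, hyper_oracle, 0, a = 6, b = 6,
                                  n_universe = 20)))
  # disjoint targets: p ~ 1
  degs3 <- list(care = universe[10:17])
  expect_gt(tf_enrichment(model, degs3, universe)$p, 0.9)
  expect_error(tf_enrichment(model, list(care = "not_in_universe"),
                             universe), "subsets")
})

test_that("opposite-direction flags require significance on both sides", {
  tabs <- function(dir1, dir2, sig1 = TRUE, sig2 = TRUE) {
    mk <- function(dir, sig) data.frame(
      gene_id = c("tfA", "gX"), log2_fold_change = c(dir, 0.2),
      p_raw = 0.001, fdr_empirical = c(if (sig) 0.001 else 0.5, 0.5),
      mean_cpm = 10)
    list(exp1 = list(c1 = mk(dir1, sig1)),
         exp2 = list(c1 = mk(dir2, sig2)))
  }
  r <- opposite_direction_report("tfA", tabs(2, -2))
  expect_true(r$opposite[["tfA"]])
  # significant in only one experiment -> not flagged
  r2 <- opposite_direction_report("tfA", tabs(2, -2, sig2 = FALSE))
  expect_false(r2$opposite[["tfA"]])
  # same direction in both -> not flagged
  r3 <- opposite_direction_report("tfA", tabs(2, 2))
  expect_false(r3$opposite[["tfA"]])
  # absent from a table -> ns
  exps <- tabs(2, -2)
  exps$exp2$c1 <- exps$exp2$c1[exps$exp2$c1$gene_id != "tfA", ]
  r4 <- opposite_direction_report("tfA", exps)
  expect_false(r4$opposite[["tfA"]])
  expect_true(all(r4$table$direction[r4$table$experiment == "exp2"] == "ns"))
})

test_that("joint two-panel fitting recovers at least the single-panel edges", {
  cfg <- sim_config(n_genes = 500, n_unique_per_stage = 2, n_carryover = 2,
                    n_additive_per_stage = 2, tf_count = 4,
                    targets_per_tf = 10, edge_noise_sd = 0.2, seed = 51)
  sim <- simulate_counts(cfg)
  tf1 <- simulate_tf_structure(cfg, sim$counts$diencephalon)
  tf2 <- simulate_tf_structure(cfg, sim$counts$telencephalon)
  joint_z <- cbind(tf1$panel$z, tf2$panel$z)
  panel_j <- structure(list(z = joint_z, tf_ids = tf1$panel$tf_ids,
                            gene_ids = rownames(joint_z), samples = NULL),
                       class = "expression_panel")
  fit1 <- fit_targets(tf1$panel)
  fit2 <- fit_targets(tf2$panel)
  fitj <- fit_targets(panel_j)
  key <- function(f) paste(f$edges$tf, f$edges$target)
  planted <- paste(tf1$edges$tf, tf1$edges$target)
  single <- intersect(union(key(fit1), key(fit2)), planted)
  expect_true(all(single %in% key(fitj)))
})
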