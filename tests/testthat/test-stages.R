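test_that("stage-unique membership follows the focal/relaxed rule", {
  # two stages, DEGs {g1,g2} and {g2}: g1 unique to stage 1
  sig <- cbind(s1 = c(TRUE, TRUE, FALSE), s2 = c(FALSE, TRUE, FALSE))
  rownames(sig) <- c("g1", "g2", "g3")
  ser <- series_from_grid(sig)
  u <- unique_genes(ser)
  expect_identical(u$sets$s1, "g1")
  expect_identical(u$sets$s2, character(0))
  # g2 is focal-significant in both stages and excluded from both
  expect_true(all(u$exclusions$gene_id == "g2"))
  expect_setequal(u$exclusions$focal_stage, c("s1", "s2"))
  # significant at 0.008 in both stages -> unique to neither
  tabs <- list(s1 = make_deg_table(rownames(sig), c(TRUE, TRUE, FALSE),
                                   sig_fdr = 0.008),
               s2 = make_deg_table(rownames(sig), c(TRUE, TRUE, FALSE),
                                   sig_fdr = 0.008))
  ser2 <- stage_series(tabs)
  u2 <- unique_genes(ser2)
  expect_length(u2$sets$s1, 0)
  expect_length(u2$sets$s2, 0)
  expect_error(unique_genes(ser, relaxed_schedule = c(0.005, 0.2)),
               "exceed")
})

test_that("tightening the DEG threshold never grows sets (monotonicity)", {
  set.seed(21)
  for (i in 1:25) {
    fdrs <- matrix(runif(20 * 5)^2, 20, 5,
                   dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:5)))
    tabs <- lapply(seq_len(5), function(s)
      data.frame(gene_id = rownames(fdrs), log2_fold_change = 1,
                 p_raw = fdrs[, s], fdr_empirical = fdrs[, s], mean_cpm = 1))
    names(tabs) <- paste0("s", 1:5)
    ser <- stage_series(tabs)
    loose <- pairwise_overlap(ser, deg_fdr = 0.3)
    tight <- pairwise_overlap(ser, deg_fdr = 0.1)
    expect_true(all(tight$size_a <= loose$size_a))
    expect_true(all(tight$overlap <= loose$overlap))
  }
})

test_that("pairwise overlap p-values match exhaustive enumeration", {
  # universe 10, |A| = 4, |B| = 5, overlap 4 -> 5/210
  sig <- matrix(FALSE, 10, 2,
                dimnames = list(sprintf("g%02d", 1:10), c("s1", "s2")))
  sig[1:4, 1] <- TRUE
  sig[c(1:4, 10), 2] <- TRUE
  ov <- pairwise_overlap(series_from_grid(sig))
  expect_equal(ov$overlap, 4)
  expect_equal(ov$p, 5 / 210)
  expect_equal(ov$p, hyper_oracle(4, 4, 5, 10))
  # disjoint small sets in a big universe -> p ~ 1
  sig2 <- matrix(FALSE, 500, 2,
                 dimnames = list(sprintf("g%03d", 1:500), c("s1", "s2")))
  sig2[1:3, 1] <- TRUE; sig2[498:500, 2] <- TRUE
  expect_gt(pairwise_overlap(series_from_grid(sig2))$p, 0.9)
  # identical sets attain the minimal achievable p; matches the brute force
  sig3 <- matrix(FALSE, 12, 2,
                 dimnames = list(sprintf("g%02d", 1:12), c("s1", "s2")))
  sig3[1:5, ] <- TRUE
  ov3 <- pairwise_overlap(series_from_grid(sig3))
  expect_equal(ov3$p, hyper_oracle(5, 5, 5, 12))
  expect_equal(ov3$p, min(vapply(0:5, hyper_oracle, 0, a = 5, b = 5,
                                 n_universe = 12)))
})

test_that("added shared membership follows the full rule set", {
  # 3 stages; gene DE in {1,3} only -> stage-1 added shared;
  # gene DE in {1,2,3} everywhere keeps the pre-screen satisfied
  sig <- matrix(FALSE, 12, 3,
                dimnames = list(sprintf("g%02d", 1:12), paste0("s", 1:3)))
  sig[1:6, 1] <- TRUE; sig[2:6, 2] <- TRUE; sig[c(1, 3:6), 3] <- TRUE
  sig[7, 2:3] <- TRUE                       # first significant at stage 2
  sig[8, c(1, 2)] <- FALSE; sig[8, 3] <- TRUE   # only final stage: no set
  # pre-screen disabled here: this block exercises the membership algebra
  asr <- added_shared(series_from_grid(sig), overlap_prescreen_fdr = 1.1)
  expect_true("g01" %in% asr$sets$s1$gene_id)      # DE in {1,3}
  expect_true("g07" %in% asr$sets$s2$gene_id)      # DE in {2,3}, not 1
  expect_false("g07" %in% asr$sets$s1$gene_id)
  expect_equal(nrow(asr$sets$s3), 0)               # final stage empty
  # preceding-stage violation: DE in {1} excludes from stage-2 set
  expect_false(any(asr$sets$s2$gene_id %in% rownames(sig)[sig[, 1]]))
})

test_that("added shared matches the brute-force rule evaluator on a hand grid", {
  set.seed(7)
  sig <- matrix(runif(12 * 5) < 0.4, 12, 5,
                dimnames = list(sprintf("g%02d", 1:12), paste0("s", 1:5)))
  asr <- added_shared(series_from_grid(sig))
  oracle <- added_shared_oracle(sig)
  for (s in paste0("s", 1:5)) {
    expect_setequal(asr$sets[[s]]$gene_id, oracle[[s]])
  }
})

test_that("concordance statistics match the analytic chance expectation", {
  # 4 genes each significant in k = 3 stages: expected concordant = 1
  toy <- structure(list(sets = list(
    s1 = data.frame(gene_id = paste0("g", 1:4), focal_stage = "s1",
                    pattern = "+++..", k = 3,
                    all_up = c(TRUE, TRUE, FALSE, FALSE),
                    all_down = c(FALSE, FALSE, TRUE, FALSE)))),
    class = "added_shared")
  ct <- concordance_test(toy)
  expect_equal(ct$pooled$expected_concordant, 1)
  expect_equal(ct$pooled$concordant, 3)
  # 10-gene toy, mixed k in {2,3}: chi-square equals the hand computation
  k <- c(2, 2, 2, 2, 3, 3, 3, 3, 3, 3)
  up <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  dn <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  toy2 <- structure(list(sets = list(
    s1 = data.frame(gene_id = paste0("g", 1:10), focal_stage = "s1",
                    pattern = "..", k = k, all_up = up, all_down = dn))),
    class = "added_shared")
  ct2 <- concordance_test(toy2)
  e_dir <- 4 * 0.25 + 6 * 0.125            # 1.75 per direction
  expect_equal(ct2$pooled$expected, c(up = e_dir, down = e_dir,
                                      discordant = 10 - 2 * e_dir))
  chi_hand <- (5 - e_dir)^2 / e_dir + (2 - e_dir)^2 / e_dir +
    (3 - (10 - 2 * e_dir))^2 / (10 - 2 * e_dir)
  expect_equal(ct2$pooled$chi_square, chi_hand)
  expect_equal(ct2$pooled$chi_df, 2)
  # k < 2 cannot be assessed
  bad <- structure(list(sets = list(
    s1 = data.frame(gene_id = "g1", focal_stage = "s1", pattern = "+",
                    k = 1, all_up = TRUE, all_down = FALSE))),
    class = "added_shared")
  expect_error(concordance_test(bad), "at least two")
})

test_that("directional set test hits its bounds and reflects", {
  set.seed(2)
  # 20 strongly positive members: the all-positive flip that would tie the
  # observed statistic has probability 2^-20, so p sits at its floor
  z <- setNames(c(rep(6, 20), rnorm(80)), paste0("g", 1:100))
  up <- directional_set_test(z, paste0("g", 1:20), "Up", n_rot = 999,
                             seed = 1)
  expect_equal(up$p, 1 / 1000)
  dn <- directional_set_test(z, paste0("g", 1:20), "Down", n_rot = 999,
                             seed = 1)
  expect_gt(dn$p, 0.99)
  expect_error(directional_set_test(z, character(0), "Up"), "empty")
})

test_that("directional set test p-values are uniform under the null", {
  set.seed(33)
  ps <- replicate(1000, {
    z <- setNames(rnorm(60), paste0("g", 1:60))
    directional_set_test(z, sample(names(z), 10), "Up", n_rot = 499)$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))$statistic
  expect_lt(unname(ks), 0.05)
})
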