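cm <- default_channel_map()
temps <- cm$temperatures_c

ratio_profile <- function(r1, r2 = NULL) {
  m <- cbind(r1, r2)
  rownames(m) <- temps[seq_len(nrow(m))]
  m
}

test_that("log2 ratios are within-replicate differences with NA propagation", {
  set.seed(1)
  base <- matrix(rnorm(20, 20, 1), nrow = 2)
  norm <- make_norm(list(mock.1 = base, mock.2 = base + 0.3,
                         lps.1 = base + 1, lps.2 = base + 1.3),
                    c("A", "B"))
  cp <- comparison_def("lps_vs_mock", "lps", "mock")
  ratios <- compute_log2_ratios(norm, cp)
  expect_equal(ratios$ratio, rep(1, 40))
  # treatment == reference -> all zero
  same <- make_norm(list(mock.1 = base, lps.1 = base), c("A", "B"))
  r0 <- compute_log2_ratios(same, comparison_def("x", "lps", "mock"))
  expect_equal(r0$ratio, rep(0, 20))
  # one side missing -> that cell missing
  norm2 <- norm
  norm2$norm_value[norm2$condition == "lps" & norm2$replicate == 2 &
                     norm2$temperature_c == 63 & norm2$protein_id == "A"] <- NA
  r2 <- compute_log2_ratios(norm2, cp)
  cell <- r2$ratio[r2$protein_id == "A" & r2$temperature_c == 63]
  expect_equal(sum(is.na(cell)), 1)
  expect_error(compute_log2_ratios(norm, comparison_def("bad", "nig", "mock")),
               "not present")
})

test_that("zero-variance profiles give exact degenerate bootstrap scores", {
  m <- ratio_profile(rep(1, 10), rep(1, 10))
  bs <- bootstrap_scores(m, n_iter = 100, seed = 1)
  expect_true(bs$eligible)
  expect_equal(bs$abundance_mean, 1)
  expect_equal(bs$abundance_sd, 0)
  expect_equal(bs$stability_mean, 0)  # sum of (1 - 1) over all temps
  expect_equal(bs$stability_sd, 0)
  expect_equal(bs$n_points, 10)
})

test_that("single-replicate profiles obey the stability identity exactly", {
  set.seed(2)
  r <- rnorm(10)
  bs <- bootstrap_scores(ratio_profile(r), n_iter = 50, seed = 3)
  ab <- mean(r[1:2])
  expect_equal(bs$abundance_mean, ab)
  expect_equal(bs$stability_mean, sum(r) - 10 * ab)  # sum_T r_T - n_T * ab
  expect_equal(bs$abundance_sd, 0)
  expect_equal(bs$stability_sd, 0)
})

test_that("bootstrap estimates match exhaustive enumeration", {
  set.seed(4)
  n_iter <- 500
  for (i in 1:8) {
    m <- ratio_profile(rnorm(10, 0.2, 0.5), rnorm(10, 0.2, 0.5))
    if (i == 8) m[c(3, 7), 2] <- NA  # partial profile still enumerable
    ex <- enumerate_bootstrap(m)
    bs <- bootstrap_scores(m, n_iter = n_iter, seed = 100 + i)
    expect_lt(abs(bs$abundance_mean - ex$abundance$mean),
              3 * se_of_mean(ex$abundance, n_iter) + 1e-12)
    expect_lt(abs(bs$stability_mean - ex$stability$mean),
              3 * se_of_mean(ex$stability, n_iter) + 1e-12)
    expect_lt(abs(bs$abundance_sd - ex$abundance$sd),
              3 * se_of_sd(ex$abundance, n_iter) + 1e-12)
    expect_lt(abs(bs$stability_sd - ex$stability$sd),
              3 * se_of_sd(ex$stability, n_iter) + 1e-12)
  }
})

test_that("profiles without two low-temperature points are skipped", {
  m <- ratio_profile(c(0.5, NA, rnorm(8)), c(NA, NA, rnorm(8)))
  expect_false(bootstrap_scores(m, n_iter = 10)$eligible)
  # two points across the two lowest temperatures suffice
  m2 <- ratio_profile(c(0.5, 0.4, rnorm(8)), c(NA, NA, rnorm(8)))
  expect_true(bootstrap_scores(m2, n_iter = 10, seed = 1)$eligible)
})

test_that("bootstrap is seed-reproducible and protein-order invariant", {
  set.seed(5)
  base <- matrix(rnorm(40, 20, 1), nrow = 4)
  norm <- make_norm(list(mock.1 = base, mock.2 = base + rnorm(40, 0, 0.2),
                         lps.1 = base + rnorm(40, 0, 0.2),
                         lps.2 = base + rnorm(40, 0, 0.2)),
                    c("P1", "P2", "P3", "P4"))
  cp <- comparison_def("lps_vs_mock", "lps", "mock")
  ratios <- compute_log2_ratios(norm, cp)
  b1 <- bootstrap_all(ratios, cm, n_iter = 200, seed = 9)
  b2 <- bootstrap_all(ratios, cm, n_iter = 200, seed = 9)
  expect_equal(b1, b2)
  shuffled <- ratios[rev(seq_len(nrow(ratios))), ]
  b3 <- bootstrap_all(shuffled, cm, n_iter = 200, seed = 9)
  expect_equal(b3$boot_mean, b1$boot_mean)
  b4 <- bootstrap_all(ratios, cm, n_iter = 200, seed = 10)
  expect_false(identical(b4$boot_mean, b1$boot_mean))
})

test_that("score p-values follow the t distribution contract", {
  expect_equal(score_pvalue(0, 1, 10), 1)
  expect_equal(score_pvalue(2, 1, 10), 2 * pt(-2, df = 9))
  expect_equal(score_pvalue(0.5, 0, 10), .Machine$double.xmin)
  expect_equal(score_pvalue(0, 0, 10), 1)
  expect_error(score_pvalue(1, 1, 1), "n_points")
  # vectorized
  p <- score_pvalue(c(0, 2), c(1, 1), c(10, 10))
  expect_equal(p, c(1, 2 * pt(-2, df = 9)))
})

test_that("z-standardization uses proteome median and scaled MAD", {
  x <- c(0, 0, 0, 0, 1, -1, 2, -2, 5, -5)
  z <- standardize_scores(x)
  expect_equal(z, (x - 0) / (1.4826 * 1))  # median 0, MAD(|x|) median = 1
  # affine invariance
  set.seed(6)
  ref <- rnorm(50)
  expect_equal(standardize_scores(2 * ref + 3), standardize_scores(ref))
  expect_error(standardize_scores(rep(1, 20)), "degenerate")
  expect_error(standardize_scores(rnorm(5)), "at least 10")
})

test_that("global FDR matches a hand-computed BH oracle under N(0,1)", {
  z <- c(3.0, -0.5, 0.1, 1.0, -2.5, 0.0, 0.3, -0.2, 0.15, -0.7)
  q <- global_fdr_from_z(z, null = "theoretical")
  p <- 2 * pnorm(-abs(z))
  # independent step-up: sorted p * n / rank, running minimum from the top
  o <- order(p)
  bh <- rev(cummin(rev(p[o] * length(p) / seq_along(p))))
  expect_equal(q[o], pmin(bh, 1))
  # all-null input: every q equals 1 when every p is 1
  expect_equal(global_fdr_from_z(c(rep(0, 11)), null = "theoretical"),
               rep(1, 11))
})

test_that("empirical null recenters and rescales before q-values", {
  set.seed(7)
  z <- rnorm(500, mean = 2, sd = 3)  # shifted, inflated null
  q <- global_fdr_from_z(z, null = "empirical")
  # bulk should look null: very few small q
  expect_lt(mean(q < 0.05), 0.01)
  expect_error(global_fdr_from_z(rep(1, 20)), "degenerate")
})

test_that("BH adjustment matches hand examples and is monotone/idempotent", {
  expect_equal(local_fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(local_fdr_bh(0.3), 0.3)
  expect_equal(local_fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  set.seed(8)
  p <- runif(100)^2
  q <- local_fdr_bh(p)
  expect_true(all(q >= p))
  expect_equal(order(q[order(p)]), seq_along(p))  # monotone in p
  expect_error(local_fdr_bh(c(0.5, 1.5)), "p-values")
})

test_that("expression scores reduce to the pooled t-test at prior_df 0", {
  set.seed(9)
  base <- matrix(rnorm(24, 20, 1), nrow = 12)
  vals <- list(mock.1 = base, mock.2 = base + rnorm(24, 0, 0.3),
               lps.1 = base + rnorm(24, 0.5, 0.3),
               lps.2 = base + rnorm(24, 0.5, 0.3))
  norm <- make_norm(vals, sprintf("P%02d", 1:12), temps = c(37, 41))
  cp <- comparison_def("lps_vs_mock", "lps", "mock")
  es <- expression_scores(norm, cp, prior_df = 0)
  for (pid in c("P01", "P07")) {
    x <- norm$norm_value[norm$protein_id == pid & norm$condition == "lps"]
    y <- norm$norm_value[norm$protein_id == pid & norm$condition == "mock"]
    tt <- t.test(x, y, var.equal = TRUE)
    row <- es[es$protein_id == pid, ]
    expect_equal(row$moderated_t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-12)
    expect_equal(row$logfc, unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("expression scores: null identity and exact shift recovery", {
  set.seed(10)
  base <- matrix(rnorm(24, 20, 1), nrow = 12)
  jit <- matrix(rnorm(24, 0, 0.2), nrow = 12)
  jit[1, ] <- 0  # P01: treatment exactly equals reference
  cp <- comparison_def("lps_vs_mock", "lps", "mock")
  same <- make_norm(list(mock.1 = base, mock.2 = base + 0.1,
                         lps.1 = base + jit, lps.2 = base + 0.1 + jit),
                    sprintf("P%02d", 1:12), temps = c(37, 41))
  es0 <- expression_scores(same, cp)
  p01 <- es0[es0$protein_id == "P01", ]
  expect_equal(p01$logfc, 0)
  expect_equal(p01$p_value, 1)
  expect_equal(p01$z, 0)
  # a +1 glog2 shift replicated exactly gives logfc = 1 for every protein
  shifted <- make_norm(list(mock.1 = base, mock.2 = base + jit,
                            lps.1 = base + 1, lps.2 = base + jit + 1),
                       sprintf("P%02d", 1:12), temps = c(37, 41))
  es1 <- expression_scores(shifted, cp)
  expect_equal(es1$logfc, rep(1, 12))
})

test_that("hit criteria apply both FDR gates and the z cutoff", {
  scores <- data.frame(protein_id = c("A", "B", "C", "D"),
                       comparison = "x", score_type = "stability",
                       z = c(2.0, 2.5, -3.0, 1.0),
                       fdr_global = c(0.04, 0.005, 0.005, 0.2),
                       fdr_local = c(0.02, 0.005, 0.02, 0.5))
  dual <- call_hits(scores, "dual_fdr_001")
  expect_equal(dual$protein_id, "B")  # both gates must pass
  alt <- call_hits(scores, "z196_fdr005")
  expect_equal(alt$protein_id, c("A", "B", "C"))
  expect_equal(alt$direction, c("stabilized", "stabilized", "destabilized"))
  empty <- call_hits(scores[0, ], "dual_fdr_001")
  expect_equal(nrow(empty), 0)
  expect_error(call_hits(scores, "no_such"), "arg")
})

test_that("spiked effects land on the right score with the right sign", {
  # destabilized (dTm = -3), stabilized (+3), and pure 2-fold abundance
  cfg <- sim_config(n_proteins = 60, conditions = c("mock", "nigericin"),
                    noise_sd = 0.05, frac_stability_hits = 0,
                    frac_abundance_hits = 0, missing_rate_high_temp = 0,
                    seed = 11)
  sim <- simulate_proteome(cfg)
  quant <- sim$quant
  tm <- sim$truth$tm_true_mock
  a <- sim$truth$curve_a
  p <- sim$truth$curve_plateau
  q <- log(0.5 / (0.5 - p))
  # rebuild nigericin intensities with handcrafted effects for P1..P3
  effects <- list(P00001 = list(dtm = -3, fc = 0),
                  P00002 = list(dtm = +3, fc = 0),
                  P00003 = list(dtm = 0, fc = 1))
  for (pid in names(effects)) {
    # pin the test proteins well above the glog noise floor so the
    # transform is effectively log2 over their whole gradient
    sel_all <- quant$protein_id == pid
    lift <- 2^24 / stats::median(quant$intensity[sel_all &
                                                   quant$temperature_c == 37])
    quant$intensity[sel_all] <- quant$intensity[sel_all] * lift
  }
  for (pid in names(effects)) {
    i <- match(pid, sim$truth$protein_id)
    ef <- effects[[pid]]
    sel <- quant$protein_id == pid & quant$condition == "nigericin"
    b2 <- a[i] / (tm[i] + ef$dtm) + q[i]
    f2 <- (1 - p[i]) / (1 + exp(-(a[i] / quant$temperature_c[sel] - b2))) +
      p[i]
    f1 <- (1 - p[i]) / (1 + exp(-(a[i] / quant$temperature_c[sel] -
                                    (a[i] / tm[i] + q[i])))) + p[i]
    quant$intensity[sel] <- quant$intensity[sel] / f1 * f2 * 2^ef$fc
  }
  norm <- remove_batch_effects(normalize_per_temperature(quant))
  cp <- comparison_def("nig_vs_mock", "nigericin", "mock")
  sc <- score_comparison(norm, cp, n_iter = 300, seed = 12)
  s <- sc$scores
  get <- function(pid, type, col)
    s[[col]][s$protein_id == pid & s$score_type == type]
  expect_lt(get("P00001", "stability", "z"), -2)
  expect_gt(get("P00002", "stability", "z"), 2)
  expect_lt(abs(get("P00001", "abundance", "z")), 1.5)
  # uniform 2-fold change: large abundance z, stability cancels baseline
  expect_gt(abs(get("P00003", "abundance", "z")), 3)
  expect_lt(abs(get("P00003", "stability", "z")), 1.5)
})
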