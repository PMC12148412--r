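temps <- default_channel_map()$temperatures_c

test_that("identical samples get unit scale factors and equal norm values", {
  prof <- matrix(rep(c(2000, 1800, 1200, 600, 200, 100, 80, 60, 50, 40),
                     each = 3) * c(1, 2, 5), nrow = 3)
  quant <- make_quant(list(mock.1 = prof, mock.2 = prof), c("A", "B", "C"))
  norm <- normalize_per_temperature(quant)
  calib <- attr(norm, "calibration")
  expect_equal(calib$scale_factor, rep(1, nrow(calib)))
  wide <- split(norm$norm_value, norm$replicate)
  expect_equal(wide[[1]], wide[[2]])
})

test_that("a doubled sample gets a doubled scale factor (median-ratio)", {
  set.seed(1)
  prof <- matrix(rlnorm(5 * 10, log(1e6), 0.5), nrow = 5)
  quant <- make_quant(list(mock.1 = prof, mock.2 = 2 * prof),
                      paste0("P", 1:5))
  norm <- normalize_per_temperature(quant)
  calib <- attr(norm, "calibration")
  s1 <- calib$scale_factor[calib$sample == "mock.1"]
  s2 <- calib$scale_factor[calib$sample == "mock.2"]
  expect_equal(s2 / s1, rep(2, 10))
  # post-scaling values equal across the two samples
  wide <- split(norm$norm_value, norm$replicate)
  expect_equal(wide[[1]], wide[[2]])
  # closed-form check at one temperature: factors are the median ratio to
  # the per-protein geometric mean, so s1 = median(x/sqrt(2 x^2)) = 1/sqrt(2)
  expect_equal(s1, rep(1 / sqrt(2), 10), tolerance = 1e-12)
})

test_that("glog2 approaches log2 for large intensities", {
  c_t <- 100
  x <- 1e9
  expect_equal(log2((x + sqrt(x^2 + c_t^2)) / 2), log2(x), tolerance = 1e-6)
})

test_that("normalization is scale-equivariant per temperature", {
  set.seed(2)
  prof1 <- matrix(rlnorm(40, log(1e6), 0.4), nrow = 4)
  prof2 <- matrix(rlnorm(40, log(1e6), 0.4), nrow = 4)
  quant <- make_quant(list(mock.1 = prof1, mock.2 = prof2), paste0("P", 1:4))
  scaled <- quant
  k <- ifelse(scaled$temperature_c == 44, 7.5, 1)
  scaled$intensity <- scaled$intensity * k
  n1 <- normalize_per_temperature(quant)
  n2 <- normalize_per_temperature(scaled)
  expect_equal(n1$norm_value, n2$norm_value, tolerance = 1e-12)
})

test_that("norm values preserve within-sample intensity order", {
  set.seed(3)
  prof1 <- matrix(rlnorm(60, log(1e5), 1), nrow = 6)
  prof2 <- matrix(rlnorm(60, log(1e5), 1), nrow = 6)
  quant <- make_quant(list(mock.1 = prof1, mock.2 = prof2), paste0("P", 1:6))
  norm <- normalize_per_temperature(quant)
  merged <- merge(quant, norm)
  for (tt in temps) {
    sub <- merged[merged$temperature_c == tt & merged$replicate == 1, ]
    expect_equal(order(sub$intensity), order(sub$norm_value))
  }
})

test_that("missing intensities stay missing and sparse temps error", {
  prof <- matrix(rlnorm(20, log(1e6)), nrow = 2)
  prof[1, 3] <- NA
  quant <- make_quant(list(mock.1 = prof, mock.2 = prof + 1), c("A", "B"))
  norm <- normalize_per_temperature(quant)
  merged <- merge(quant, norm)
  expect_equal(is.na(merged$norm_value), is.na(merged$intensity))
  one_sample <- quant[quant$replicate == 1, ]
  expect_error(normalize_per_temperature(one_sample), "fewer than 2")
})

test_that("an additive replicate offset is removed exactly", {
  set.seed(4)
  base <- matrix(rnorm(50, 20, 2), nrow = 5)
  delta <- 0.7
  norm <- make_norm(list(mock.1 = base, mock.2 = base + delta,
                         lps.1 = base, lps.2 = base + delta),
                    paste0("P", 1:5))
  adj <- remove_batch_effects(norm)
  # closed-form two-group least squares: batch-2 coefficient = delta,
  # removed from replicate 2; replicate 1 (reference batch) untouched
  r1 <- adj$norm_value[adj$replicate == 1]
  r2 <- adj$norm_value[adj$replicate == 2]
  expect_equal(max(abs(r2 - r1)), 0, tolerance = 1e-9)
  expect_equal(adj$norm_value[adj$replicate == 1],
               norm$norm_value[norm$replicate == 1], tolerance = 1e-12)
})

test_that("condition differences survive batch removal unchanged", {
  set.seed(5)
  base <- matrix(rnorm(30, 20, 2), nrow = 3)
  Delta <- 1.3
  norm <- make_norm(list(mock.1 = base, mock.2 = base + 0.7,
                         lps.1 = base + Delta, lps.2 = base + Delta + 0.7),
                    paste0("P", 1:3))
  adj <- remove_batch_effects(norm)
  m <- tapply(adj$norm_value, adj$condition, mean)
  expect_equal(unname(m["lps"] - m["mock"]), Delta, tolerance = 1e-9)
})

test_that("batch removal is idempotent and a single batch is a no-op", {
  set.seed(6)
  base <- matrix(rnorm(40, 20, 2), nrow = 4)
  norm <- make_norm(list(mock.1 = base, mock.2 = base + 0.4,
                         lps.1 = base - 0.2, lps.2 = base + 0.1),
                    paste0("P", 1:4))
  once <- remove_batch_effects(norm)
  twice <- remove_batch_effects(once)
  expect_equal(twice$norm_value, once$norm_value, tolerance = 1e-9)
  single <- norm[norm$replicate == 1, ]
  same <- remove_batch_effects(single)
  expect_equal(same$norm_value, single$norm_value, tolerance = 1e-12)
})

test_that("batch removal matches the reference limma implementation", {
  skip_if_not_installed("limma")
  set.seed(7)
  base <- matrix(rnorm(60, 20, 2), nrow = 6)
  norm <- make_norm(list(mock.1 = base + 0.1, mock.2 = base + 0.9,
                         lps.1 = base - 0.3, lps.2 = base + 0.5),
                    paste0("P", 1:6))
  adj <- remove_batch_effects(norm)
  # assemble protein x sample matrices per temperature and compare
  norm$sample <- paste(norm$condition, norm$replicate, sep = ".")
  adj$sample <- paste(adj$condition, adj$replicate, sep = ".")
  for (tt in c(37, 50)) {
    sub <- norm[norm$temperature_c == tt, ]
    m <- tapply(sub$norm_value, list(sub$protein_id, sub$sample), mean)
    batch <- sub("^.*\\.", "", colnames(m))
    cond <- sub("\\..*$", "", colnames(m))
    ref <- limma::removeBatchEffect(m, batch = batch,
                                    design = stats::model.matrix(~cond))
    suba <- adj[adj$temperature_c == tt, ]
    ma <- tapply(suba$norm_value, list(suba$protein_id, suba$sample), mean)
    # limma centers batch terms (sum-to-zero), this package zeroes the
    # reference batch: results agree up to a per-protein constant
    expect_equal(unname(ma - rowMeans(ma)), unname(ref - rowMeans(ref)),
                 tolerance = 1e-9)
  }
})

test_that("batch confounded with condition raises an error", {
  base <- matrix(rnorm(20, 20, 2), nrow = 2)
  norm <- make_norm(list(mock.1 = base, lps.2 = base + 1), c("A", "B"))
  expect_error(remove_batch_effects(norm), "confounded")
})
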