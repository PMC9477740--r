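# Preprocessing chain: mixing correction, filters, averaging, imputation,
# batch normalization, replicate correlation.

test_that("mixing correction scales channels by total over median total", {
  m <- matrix(1, 3, 4)
  expect_equal(correct_mixing(m, c(2, 2, 2, 2)), m)
  out <- correct_mixing(m, c(2, 1, 1, 1))
  expect_equal(out[, 1], rep(0.5, 3))
  expect_equal(out[, 2:4], m[, 2:4])
  expect_error(correct_mixing(m, c(1, 0, 1, 1)), "channel")

  # within-channel rank order of sites is preserved
  set.seed(1)
  r <- matrix(rexp(40, 1 / 1e6), 10, 4)
  cr <- correct_mixing(r, runif(4, 0.5, 2))
  for (j in 1:4) expect_equal(order(cr[, j]), order(r[, j]))
})

test_that("localization filter keeps sites with max replicate score >= threshold", {
  sites <- data.frame(site_id = c("a", "b", "c"),
                      loc_score_rep1 = c(60, 74, 75),
                      loc_score_rep2 = c(80, 74.9, NA))
  kept <- filter_localization(sites, 75)
  expect_setequal(kept$site_id, c("a", "c"))
  expect_identical(filter_localization(kept, 75), kept)
})

test_that("fraction partition removes pS/pT from pY-IP and cross-listed pY from TiO2", {
  sites <- data.frame(
    site_id = c("s1", "y1", "y1", "y2", "s2"),
    residue = c("S", "Y", "Y", "Y", "S"),
    fraction = c("pY-IP", "pY-IP", "TiO2", "TiO2", "TiO2"))
  out <- partition_fractions(sites)
  # S-site dropped from pY-IP; y1 kept in pY-IP only; y2 (TiO2-only) kept
  expect_equal(nrow(out), 3)
  expect_true(all(out$residue[out$fraction == "pY-IP"] == "Y"))
  expect_equal(sum(out$site_id == "y1"), 1)
  expect_equal(out$fraction[out$site_id == "y1"], "pY-IP")
  expect_true("y2" %in% out$site_id[out$fraction == "TiO2"])
  expect_false(any(duplicated(out$site_id)))
  expect_identical(partition_fractions(out), out)
})

test_that("technical replicates average on the log2 scale over observed values", {
  vals <- matrix(c(10, 12, 10, NA, 7, 7), nrow = 1)
  pset <- toy_pset(vals, ligand = rep("unstim", 6), time = 0,
                   biorep = c(1, 1, 2, 2, 3, 3), channel = c(1, 1, 2, 2, 3, 3),
                   techrep = c(1, 2, 1, 2, 1, 2))
  avg <- average_technical_replicates(pset)
  expect_equal(unname(avg$log2[1, ]), c(11, 10, 7))
  single <- toy_pset(matrix(c(5, 6), 1), ligand = rep("unstim", 2), time = 0,
                     biorep = 1:2)
  expect_equal(unname(average_technical_replicates(single)$log2[1, ]), c(5, 6))
})

test_that("imputation fills only fully missing conditions, from N(q05, sd)", {
  # condition with one observed replicate: untouched
  vals <- matrix(c(10, NA, NA, 11, 11.5, 12), nrow = 1)
  pset <- toy_pset(vals, ligand = c(rep("N4", 3), rep("unstim", 3)),
                   time = c(30, 30, 30, 0, 0, 0), biorep = c(1:3, 1:3))
  out <- impute_condition_missing(pset, seed = 1)
  expect_identical(out$log2, pset$log2)

  # no missing values: identity, zero imputed flags
  full <- toy_pset(matrix(rnorm(12, 20), 2), ligand = rep(c("unstim", "N4"), each = 3),
                   time = rep(c(0, 30), each = 3), biorep = rep(1:3, 2))
  outf <- impute_condition_missing(full, seed = 1)
  expect_identical(outf$log2, full$log2)
  expect_true(all(outf$observed))

  # Monte-Carlo: imputed draws match the stated Gaussian
  set.seed(99)
  n_sites <- 2500
  obs <- matrix(rnorm(n_sites * 3, 24, 2), n_sites, 3)
  vals <- cbind(obs, matrix(NA_real_, n_sites, 4))
  pset <- toy_pset(vals, ligand = c(rep("unstim", 3), rep("N4", 4)),
                   time = c(0, 0, 0, rep(30, 4)), biorep = c(1:3, 1:4))
  q05 <- unname(quantile(obs, 0.05))
  sd_all <- sd(obs)
  out <- impute_condition_missing(pset, seed = 123)
  imputed <- out$log2[, 4:7]
  expect_equal(length(imputed), 10000)
  expect_lt(abs(mean(imputed) - q05), 0.07)
  expect_lt(abs(sd(imputed) - sd_all), 0.05)
  # observed cells untouched; imputed flags tile exactly the missing block
  expect_identical(out$log2[, 1:3], pset$log2[, 1:3])
  expect_identical(unname(out$observed), cbind(matrix(TRUE, n_sites, 3),
                                               matrix(FALSE, n_sites, 4)))
})

test_that("all-missing input cannot define the imputation model", {
  empty <- toy_pset(matrix(NA_real_, 2, 2), ligand = c("unstim", "N4"),
                    time = c(0, 30), biorep = c(1, 1))
  expect_error(impute_condition_missing(empty), "no observed")
})

test_that("batch normalization removes injected offsets and is shift-only", {
  # flat site, three batches of (unstim, N4) with offsets 0, +2, -1
  offsets <- c(0, 2, -1)
  vals <- matrix(10 + rep(offsets, each = 2), nrow = 1)
  pset <- toy_pset(vals, ligand = rep(c("unstim", "N4"), 3),
                   time = rep(c(0, 30), 3), biorep = rep(1:3, each = 2),
                   batch = rep(1:3, each = 2), channel = rep(1:2, 3))
  out <- normalize_batches(pset)
  est <- pset$log2[1, ] - out$log2[1, ]           # removed shift per column
  expect_equal(unname(est) - rep(offsets, each = 2),
               rep(mean(est) - mean(rep(offsets, each = 2)), 6),
               tolerance = 1e-12)
  bm <- tapply(out$log2[1, ], rep(1:3, each = 2), mean)
  expect_equal(unname(diff(range(bm))), 0, tolerance = 1e-12)

  # batch 2 = batch 1 + 1: shared-condition means coincide afterwards
  v2 <- rbind(c(8, 9, 9, 10), c(20, 21, 21, 22))
  p2 <- toy_pset(v2, ligand = rep(c("unstim", "N4"), 2),
                 time = rep(c(0, 30), 2), biorep = rep(1:2, each = 2),
                 batch = rep(1:2, each = 2), channel = rep(1:2, 2))
  o2 <- normalize_batches(p2)
  for (i in 1:2) {
    m <- tapply(o2$log2[i, ], rep(1:2, each = 2), mean)
    expect_equal(unname(m[1]), unname(m[2]), tolerance = 1e-12)
    # shift-only: within-batch differences unchanged
    expect_equal(diff(o2$log2[i, 1:2]), diff(p2$log2[i, 1:2]),
                 ignore_attr = TRUE)
  }

  # single batch: unchanged
  one <- toy_pset(matrix(1:4, 1), ligand = c("unstim", "N4", "T4", "T4"),
                  time = c(0, 30, 30, 120), biorep = 1)
  expect_identical(normalize_batches(one)$log2, one$log2)
})

test_that("sample correlation is Pearson over pairwise-complete pairs", {
  x <- c(1, 2, 3); y <- c(1, 3, 2)
  m <- cbind(a = x, b = x, c = -x, d = y, e = rep(5, 3))
  r <- sample_correlation(m)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["a", "d"], 0.5)
  expect_true(is.na(r["a", "e"]))
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_equal(r, t(r))
})
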