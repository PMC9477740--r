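# AP-MS scoring: cleaning, normalization, Welch tests, volcano FDR,
# interactor calls, stoichiometry.

test_that("protein-group cleaning filters and merges by gene", {
  intens <- rbind(c(3e6, 2e6), c(1e6, 4e6), c(5e6, 5e6), c(7e6, 7e6))
  pg <- toy_pg(intens, genotype = c("OST", "WT"), ligand = "unstim",
               time = 0, biorep = 1,
               prey_ids = c("geneX", "geneX", "bad", "dirt"),
               score = c(100, 50, -1, 80),
               contaminant = c(FALSE, FALSE, FALSE, TRUE))
  out <- clean_protein_groups(pg)
  expect_equal(out$preys$prey_id, "geneX")
  expect_equal(unname(out$intensity[1, ]), c(4e6, 6e6))
})

test_that("median normalization equalizes sample medians", {
  m <- cbind(c(1, 2, 3), c(2, 4, 6), c(4, 8, 16))   # medians 2, 4, 8
  pg <- toy_pg(m, genotype = "OST", ligand = "unstim", time = 0, biorep = 1:3)
  out <- median_normalize(pg)
  meds <- apply(out$intensity, 2, median)
  expect_equal(unname(meds), rep(4, 3), tolerance = 1e-12)
  expect_equal(unname(out$intensity[, 1]), c(2, 4, 6))
  already <- toy_pg(cbind(c(1, 2, 3), c(0.5, 2, 9)), genotype = "OST",
                    ligand = "unstim", time = 0, biorep = 1:2)
  expect_equal(median_normalize(already)$intensity, already$intensity,
               tolerance = 1e-12)
  m2 <- m; m2[, 2] <- NA
  pg2 <- toy_pg(m2, genotype = "OST", ligand = "unstim", time = 0, biorep = 1:3)
  expect_error(median_normalize(pg2), "observed")
})

test_that("technical averaging uses the geometric mean over observed values", {
  m <- matrix(c(4, 9, 8, NA, 5, 5), nrow = 1)
  pg <- toy_pg(m, genotype = "OST", ligand = "unstim", time = 0,
               biorep = c(1, 1, 2, 2, 3, 3))
  pg$samples$techrep <- c(1L, 2L, 1L, 2L, 1L, 2L)
  pg$samples$sample_id <- paste(pg$samples$bait, pg$samples$genotype,
                                pg$samples$ligand, pg$samples$time,
                                pg$samples$biorep, pg$samples$techrep,
                                sep = ".")
  out <- average_technical_geomean(pg)
  expect_equal(unname(out$intensity[1, ]), c(6, 8, 5))
})

welch_pg <- function(ost, wt) {
  toy_pg(matrix(2^c(ost, wt), nrow = 1),
         genotype = rep(c("OST", "WT"), c(length(ost), length(wt))),
         ligand = rep(c("N4", "unstim"), c(length(ost), length(wt))),
         time = rep(c(30, 0), c(length(ost), length(wt))),
         biorep = c(seq_along(ost), seq_along(wt)))
}

test_that("Welch testing reproduces the two-sample t-test", {
  pg <- welch_pg(c(10, 11, 12), c(13, 14, 15))
  res <- test_interactions(pg, n_repeats = 10, seed = 1)
  expect_equal(res$log2fc, -3)
  ref <- t.test(c(10, 11, 12), c(13, 14, 15))
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(res$p, 0.0213, tolerance = 1e-3)

  same <- test_interactions(welch_pg(c(10, 11, 12), c(10, 11, 12)),
                            seed = 1)
  expect_equal(same$p, 1)
  expect_equal(same$log2fc, 0)
})

test_that("with complete data the imputation repeats are a fixed point", {
  pg <- welch_pg(c(20, 21, 22), c(18, 18.5, 19))
  one <- test_interactions(pg, n_repeats = 1, seed = 1)
  ten <- test_interactions(pg, n_repeats = 10, seed = 99)
  expect_equal(one$p, ten$p, tolerance = 1e-12)
  expect_equal(one$log2fc, ten$log2fc, tolerance = 1e-12)
})

test_that("p-value aggregation across repeats is the geometric mean", {
  expect_equal(tcrdiscrim:::geomean(c(0.01, 0.04)), 0.02, tolerance = 1e-12)
})

test_that("volcano-asymmetry FDR follows the mirrored-count estimator", {
  # perfectly mirror-symmetric volcano: every positive candidate gets 1
  sym <- data.frame(log2fc = c(1, 2, 3, -1, -2, -3),
                    p = rep(0.01, 6))
  expect_equal(asymmetry_fdr(sym)$fdr, rep(1, 6))
  # no negative points at any stringency: fdr 0 for positives
  posonly <- data.frame(log2fc = c(2, 4), p = c(0.01, 0.001))
  expect_equal(asymmetry_fdr(posonly)$fdr, c(0, 0))
  # 4 positive points and one mirror at the same stringency: 1/4
  quad <- data.frame(log2fc = c(rep(4, 4), -4), p = rep(0.001, 5))
  expect_equal(asymmetry_fdr(quad)$fdr, c(rep(0.25, 4), 1))
  # negative fold changes always receive fdr 1
  expect_equal(asymmetry_fdr(data.frame(log2fc = -2, p = 1e-9))$fdr, 1)
})

test_that("monotonized FDR is non-increasing with increasing stringency", {
  set.seed(5)
  for (i in 1:10) {
    d <- data.frame(log2fc = rnorm(120, 0.2, 2),
                    p = rbeta(120, 0.4, 2))
    out <- asymmetry_fdr(d)
    pos <- out[out$log2fc > 0, ]
    targets <- vapply(seq_len(nrow(pos)), function(j)
      sum(out$log2fc >= pos$log2fc[j] & out$p <= pos$p[j]), numeric(1))
    ord <- order(targets)          # most stringent first
    expect_true(all(diff(pos$fdr[ord]) >= -1e-12))
    expect_true(all(out$fdr >= 0 & out$fdr <= 1))
  }
})

test_that("interactor calls need one condition past both thresholds", {
  tests <- data.frame(prey_id = c("a", "a", "b", "c"),
                      log2fc = log2(c(12, 2, 9, 12)),
                      fdr = c(0.01, 0.8, 0.001, 0.06))
  out <- call_interactors(tests)
  expect_true(all(out$interactor[out$prey_id == "a"]))
  expect_false(any(out$interactor[out$prey_id == "b"]))  # FC too small
  expect_false(any(out$interactor[out$prey_id == "c"]))  # FDR too large
})

test_that("interaction stoichiometry is the iBAQ-normalized prey:bait ratio", {
  # zero background (no WT signal), one condition
  m <- cbind(c(1e8, 4e8), c(0, 0))
  pg <- toy_pg(m, genotype = c("OST", "WT"), ligand = "unstim", time = 0,
               biorep = 1, prey_ids = c("prey", "bait"))
  pg$preys$n_peptides <- c(10, 20)
  st <- interaction_stoichiometry(pg, "bait")
  expect_equal(st$stoichiometry, 0.5)
  # the bait against itself has stoichiometry 1
  st_self <- interaction_stoichiometry(pg, "bait", prey_ids = "bait")
  expect_equal(st_self$stoichiometry, 1)
  # display values are row-max normalized
  m3 <- cbind(c(1e7, 4e8), c(2e7, 4e8), c(4e7, 4e8), c(0, 0))
  pg3 <- toy_pg(m3, genotype = c(rep("OST", 3), "WT"),
                ligand = c("N4", "N4", "N4", "unstim"),
                time = c(30, 120, 300, 0), biorep = 1,
                prey_ids = c("prey", "bait"))
  st3 <- interaction_stoichiometry(pg3, "bait")
  expect_equal(sort(st3$display_value), c(0.25, 0.5, 1))
  expect_equal(max(st3$display_value), 1)
})

test_that("stoichiometry is invariant to per-sample intensity rescaling", {
  sim <- simulate_apms_dataset(apms_sim_config(n_preys = 25,
                                               n_true_interactors = 3,
                                               seed = 6))
  pg <- average_technical_geomean(median_normalize(clean_protein_groups(sim$pg)))
  st1 <- interaction_stoichiometry(pg, "Cd3z")
  scaled <- sim$pg
  scaled$intensity[, 3] <- scaled$intensity[, 3] * 7.5
  pg2 <- average_technical_geomean(median_normalize(clean_protein_groups(scaled)))
  st2 <- interaction_stoichiometry(pg2, "Cd3z")
  expect_equal(st1$stoichiometry, st2$stoichiometry, tolerance = 1e-10)
})

test_that("stoichiometry discrimination recovers identity and N4-only patterns", {
  base <- data.frame(ligand = c("unstim", rep(c("N4", "T4", "G4"), each = 3)),
                     time = c(0, rep(c(30, 120, 300), 3)))
  # identical (responsive) kinetics for all three ligands: no loss
  ident <- base
  ident$stoichiometry <- ifelse(base$ligand == "unstim", 0.2,
                                0.2 * 2^rep(c(1, 2, 1), 3))
  expect_equal(stoichiometry_discrimination(ident)$score, 0)
  n4only <- base
  n4only$stoichiometry <- ifelse(base$ligand == "N4", 0.2 * 2^c(1, 2, 1), 0.2)
  expect_equal(stoichiometry_discrimination(n4only)$score, 100)
})

test_that("stoichiometry discrimination recovers the generated score", {
  truth <- data.frame(prey_id = c("prey001", sprintf("prey%03d", 2:30)),
                      is_true_interactor = c(TRUE, rep(FALSE, 29)),
                      base_stoich = c(0.02, rep(0, 29)),
                      peak_stoich = c(0.4, rep(0, 29)),
                      peak_time = 120,
                      loss_t4 = c(40, rep(NA, 29)),
                      loss_g4 = c(60, rep(NA, 29)),
                      true_score = c(50, rep(NA, 29)))
  recovered <- vapply(1:20, function(s) {
    cfg <- apms_sim_config(n_preys = 30, n_true_interactors = 1,
                           noise_sd = 0.1, true_stoich_kinetics = truth,
                           seed = s)
    sim <- simulate_apms_dataset(cfg)
    pg <- average_technical_geomean(median_normalize(clean_protein_groups(sim$pg)))
    st <- interaction_stoichiometry(pg, "Cd3z", "prey001")
    stoichiometry_discrimination(st)$score
  }, numeric(1))
  expect_true(all(abs(recovered - 50) <= 10))
})
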