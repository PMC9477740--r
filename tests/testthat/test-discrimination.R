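# Discrimination score, classification, kinetic groups, enrichment.

test_that("fold-change kinetics subtract the unstimulated mean componentwise", {
  # 2 unstim reps (mean 10), one rep per N4 time with means (10,11,12,11,10.5)
  vals <- matrix(c(9.5, 10.5, 10, 11, 12, 11, 10.5), nrow = 1)
  pset <- toy_pset(vals, ligand = c("unstim", "unstim", rep("N4", 5)),
                   time = c(0, 0, 30, 60, 120, 300, 600), biorep = c(1:2, rep(1, 5)))
  # use a grid matching the stimulated times actually present
  fc <- fold_change_kinetics(pset, "N4", times = c(0, 30, 60, 120, 300, 600))
  expect_equal(unname(fc[1, ]), c(0, 0, 1, 2, 1, 0.5))
})

test_that("trapezoidal AUC matches hand values and a fine-grid oracle", {
  times <- c(0, 30, 120, 300, 600)
  expect_equal(response_auc(rep(0, 5), times), 0)
  expect_equal(response_auc(c(0, 1, 1, 1, 1), times), 585)
  expect_equal(response_auc(times / 600, times), 300)
  set.seed(4)
  for (i in 1:20) {
    prof <- rnorm(5)
    fine_t <- seq(0, 600, length.out = 100001)
    fine <- approx(times, prof, xout = fine_t)$y
    expect_lt(abs(response_auc(prof, times) - pracma::trapz(fine_t, fine)),
              1e-9 * (1 + abs(response_auc(prof, times))))
  }
  # matrix input integrates row-wise
  m <- rbind(c(0, 1, 1, 1, 1), rep(0, 5))
  expect_equal(unname(response_auc(m, times)), c(585, 0))
})

test_that("discrimination score is the average clipped response loss", {
  ds <- discrimination_score(5.2, 9.3, 14.6)
  expect_equal(round(ds$loss_g4), 64)
  expect_equal(round(ds$loss_t4), 36)
  expect_equal(round(ds$score), 50)

  expect_equal(discrimination_score(7, 7, 7)$score, 0)
  expect_equal(discrimination_score(0, 0, 14.6)$score, 100)
  expect_equal(discrimination_score(16, 16, 14.6)$score, 0)   # clipped
  expect_true(is.na(discrimination_score(1, 1, 0)$score))     # not N4-responsive
  expect_true(is.na(discrimination_score(1, 1, -2)$score))
  # one missing weak ligand: score = the available loss
  expect_equal(discrimination_score(NA, 5, 10)$score, 50)
})

test_that("the discrimination score is invariant to AUC rescaling", {
  set.seed(11)
  for (i in 1:25) {
    a <- sort(runif(3, 0.1, 20))
    lambda <- runif(1, 1e-3, 1e3)
    expect_equal(discrimination_score(a[1], a[2], a[3]),
                 discrimination_score(lambda * a[1], lambda * a[2],
                                      lambda * a[3]),
                 tolerance = 1e-12)
  }
})

test_that("score ranges and class boundaries follow the taxonomy", {
  set.seed(3)
  sc <- discrimination_score(runif(200, -5, 30), runif(200, -5, 30),
                             runif(200, -5, 30))$score
  sc <- sc[!is.na(sc)]
  expect_true(all(sc >= 0 & sc <= 100))
  expect_equal(classify_response(c(0, 40, 50, 80, 80.01, 95, 100)),
               c("Unaffected", "Unaffected", "Gradual", "Gradual",
                 "Digital", "Digital", "Digital"))
  expect_true(is.na(classify_response(NA)))
})

test_that("sign alignment makes down-regulated sites score like up-regulated ones", {
  times <- c(0, 30, 120, 300, 600)
  up <- list(N4 = matrix(c(0, 1, 2, 1, 0.5), 1),
             T4 = matrix(c(0, 0.5, 1, 0.5, 0.25), 1),
             G4 = matrix(rep(0, 5), 1))
  down <- lapply(up, function(p) -p)
  sc_up <- with(align_profiles(up, times), discrimination_score(
    response_auc(profiles$G4, times), response_auc(profiles$T4, times),
    response_auc(profiles$N4, times)))
  sc_dn <- with(align_profiles(down, times), discrimination_score(
    response_auc(profiles$G4, times), response_auc(profiles$T4, times),
    response_auc(profiles$N4, times)))
  expect_equal(sc_up, sc_dn, tolerance = 1e-12)
  expect_equal(sc_up$loss_t4, 50)
  expect_equal(sc_up$loss_g4, 100)
})

test_that("kinetic groups separate well-resolved archetypes and tile the sites", {
  set.seed(8)
  times <- c(0, 30, 120, 300, 600)
  early <- t(sapply(1:10, function(i)
    2 * pulse_response(times, 30) + rnorm(5, 0, 0.1)))
  late <- t(sapply(1:10, function(i)
    2 * pulse_response(times, 600) + rnorm(5, 0, 0.1)))
  prof <- rbind(early, late)
  rownames(prof) <- sprintf("s%02d", 1:20)
  classes <- rep("Gradual", 20)
  grp <- suppressMessages(partition_groups(prof, classes, n_clusters = 2))
  lab <- grp$cluster[match(rownames(prof), grp$site_id)]
  expect_equal(length(unique(lab[1:10])), 1)
  expect_equal(length(unique(lab[11:20])), 1)
  expect_false(lab[1] == lab[11])
  # partition: every site appears exactly once
  expect_setequal(grp$site_id, rownames(prof))
  expect_equal(anyDuplicated(grp$site_id), 0L)

  # identical profiles within a class occupy a single cluster
  same <- matrix(rep(c(0, 1, 2, 1, 0), each = 6), nrow = 6)
  rownames(same) <- sprintf("t%02d", 1:6)
  g2 <- suppressMessages(partition_groups(same, rep("Digital", 6)))
  expect_equal(length(unique(g2$cluster)), 1)
  # group ids of the three classes occupy disjoint 4-wide bands
  expect_true(all(g2$group_id > 8 & g2$group_id <= 12))
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  # constructed universe: N = 20 scored sites, bin [0,10] holds n = 4,
  # kinase has K = 5 substrates of which k = 3 in the bin
  scores <- setNames(c(rep(5, 4), rep(95, 16)), sprintf("s%02d", 1:20))
  map <- list(KIN = c("s01", "s02", "s03", "s05", "s06"))
  enr <- kinase_enrichment(map, scores)
  cell <- enr[enr$bin_lo == 0, ]
  expect_equal(cell$k, 3); expect_equal(cell$n, 4)
  expect_equal(cell$K, 5); expect_equal(cell$N, 20)
  expect_equal(cell$p, 155 / 4845, tolerance = 1e-12)
  expect_equal(cell$fold_enrichment, 3)
  expect_true(cell$significant)
  # empty bins report n = 0, p = 1; bins without substrates fold 0
  empty <- enr[enr$bin_lo == 40, ]
  expect_equal(empty$n, 0); expect_equal(empty$p, 1)
  top <- enr[enr$bin_lo == 90, ]
  expect_equal(top$k, 2)
  expect_false(top$significant)  # fold (2/16)/(5/20) = 0.5 < 2
  expect_true(top$depleted)

  # whole-universe bin: fold 1, p = 1 when k = K
  enr1 <- kinase_enrichment(map, scores, bin_width = 100)
  expect_equal(enr1$fold_enrichment, 1)
  expect_equal(enr1$p, 1)

  # randomized instances against the enumeration oracle
  set.seed(12)
  for (i in 1:40) {
    N <- sample(5:30, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    sc <- setNames(c(rep(5, n), rep(95, N - n)), sprintf("r%02d", 1:N))
    subs <- sample(names(sc), K)
    e <- kinase_enrichment(list(k = subs), sc, bin_width = 50)
    k_in <- e$k[e$bin_lo == 0]
    expect_equal(e$p[e$bin_lo == 0], oracle_hyper_tail(k_in, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("a kinase biased to Digital sites enriches only above the 80% bins", {
  run <- default_phospho_run()
  scores <- setNames(run$scores$score, run$scores$site_id)
  truth <- run$sim$truth
  digital <- intersect(names(scores),
                       truth$site_id[truth$true_class == "Digital"])
  map <- simulate_kinase_map(6, 10, names(scores), seed = 5,
                             biased_kinase = "KIN01", biased_pool = digital)
  enr <- kinase_enrichment(map, scores)
  sig <- enr[enr$kinase == "KIN01" & enr$significant, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$bin_lo >= 80))
})
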