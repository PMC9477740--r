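#' Clean a protein-group table
#'
#' Removes protein groups with a negative identification score and groups
#' flagged as contaminants, then sums intensities per sample over rows
#' sharing the same prey (gene) id. For merged rows the molar mass of the
#' highest-scoring row and the largest theoretical-peptide count are kept.
#'
#' @param pg a [protein_groups()] table.
#' @return the cleaned [protein_groups()] table.
#' @export
clean_protein_groups <- function(pg) {
  keep <- pg$preys$score >= 0 & !pg$preys$contaminant
  intens <- pg$intensity[keep, , drop = FALSE]
  preys <- pg$preys[keep, , drop = FALSE]
  if (anyDuplicated(preys$prey_id)) {
    ids <- unique(preys$prey_id)
    merged <- matrix(NA_real_, length(ids), ncol(intens),
                     dimnames = list(ids, colnames(intens)))
    ann <- preys[0, ]
    for (i in seq_along(ids)) {
      rows <- which(preys$prey_id == ids[i])
      sub <- intens[rows, , drop = FALSE]
      s <- colSums(sub, na.rm = TRUE)
      s[colSums(!is.na(sub)) == 0] <- NA_real_
      merged[i, ] <- s
      top <- rows[which.max(preys$score[rows])]
      rec <- preys[top, , drop = FALSE]
      rec$n_peptides <- max(preys$n_peptides[rows])
      ann <- rbind(ann, rec)
    }
    intens <- merged
    preys <- ann
    rownames(preys) <- NULL
  }
  protein_groups(intens, pg$samples, preys)
}

#' Median-normalize sample intensities
#'
#' Scales each sample so its observed median intensity equals the median
#' of all sample medians; afterwards all sample medians are equal.
#'
#' @param pg a [protein_groups()] table.
#' @return the normalized [protein_groups()] table.
#' @export
median_normalize <- function(pg) {
  med <- apply(pg$intensity, 2, median, na.rm = TRUE)
  if (any(!is.finite(med)))
    stop("sample(s) without any observed intensity: ",
         paste(colnames(pg$intensity)[!is.finite(med)], collapse = ", "))
  target <- median(med)
  pg$intensity <- sweep(pg$intensity, 2, target / med, "*")
  pg
}

#' Average technical replicates (geometric mean)
#'
#' Collapses columns that differ only in their technical-replicate index
#' to the geometric mean over observed intensities.
#'
#' @param pg a [protein_groups()] table.
#' @return a [protein_groups()] table with one column per biological
#'   replicate.
#' @export
average_technical_geomean <- function(pg) {
  ann <- pg$samples
  key <- paste(ann$bait, ann$genotype, ann$ligand, ann$time, ann$biorep,
               sep = ".")
  groups <- split(seq_len(ncol(pg$intensity)),
                  factor(key, levels = unique(key)))
  lg <- log2(pg$intensity)
  vals <- vapply(groups, function(cols)
    2^rowMeans(lg[, cols, drop = FALSE], na.rm = TRUE),
    numeric(nrow(lg)))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(lg))
  vals[is.nan(vals)] <- NA_real_
  new_ann <- ann[!duplicated(key), , drop = FALSE]
  new_ann$techrep <- 1L
  rownames(new_ann) <- NULL
  colnames(vals) <- names(groups)
  protein_groups(as.matrix(vals), new_ann, pg$preys)
}

# per-prey background-imputation model fitted on observed WT log2
# intensities; preys with fewer than two WT observations fall back to the
# global low-intensity model (5% quantile mean, pooled s.d.)
wt_background_model <- function(lg, wt_cols) {
  wt <- lg[, wt_cols, drop = FALSE]
  n_obs <- rowSums(!is.na(wt))
  mu <- rowMeans(wt, na.rm = TRUE)
  s <- sqrt(row_vars(wt))
  all_wt <- wt[!is.na(wt)]
  if (!length(all_wt)) stop("no observed WT intensities")
  g_mu <- unname(quantile(all_wt, 0.05))
  g_sd <- sd(all_wt)
  mu[n_obs < 2] <- g_mu
  s[n_obs < 2 | !(s > 0)] <- g_sd
  list(mu = mu, sd = s)
}

#' Welch tests of OST enrichment with repeated imputation
#'
#' For each prey and each condition of stimulation, compares log2
#' intensities of the OST samples of that condition with the WT
#' intensities pooled over all conditions, by a two-tailed Welch t-test.
#' Missing values are imputed from the prey's WT-derived background
#' distribution; the impute-then-test cycle is repeated `n_repeats`
#' times and the fold change and p-value are aggregated as geometric
#' means across repeats (arithmetic mean on the log2 fold-change scale).
#' With no missing values the repeats are identical and the aggregation
#' is a fixed point.
#'
#' @param pg a cleaned, normalized [protein_groups()] table (technical
#'   replicates averaged).
#' @param n_repeats imputation/test repeats, default 10.
#' @param seed integer seed for the imputation draws.
#' @param exclude_preys prey ids excluded from testing (e.g. the bait).
#' @return data.frame with one row per prey x condition: `prey_id`,
#'   `ligand`, `time`, `log2fc`, `p`.
#' @export
test_interactions <- function(pg, n_repeats = 10, seed = 1L,
                              exclude_preys = character(0)) {
  keep <- !(pg$preys$prey_id %in% exclude_preys)
  lg <- log2(pg$intensity[keep, , drop = FALSE])
  preys <- pg$preys$prey_id[keep]
  ann <- pg$samples
  wt_cols <- ann$genotype == "WT"
  ost <- which(ann$genotype == "OST")
  conds <- unique(ann[ost, c("ligand", "time")])
  model <- wt_background_model(lg, wt_cols)
  na_idx <- which(is.na(lg), arr.ind = TRUE)

  n_prey <- nrow(lg)
  n_cond <- nrow(conds)
  sum_fc <- matrix(0, n_prey, n_cond)
  sum_logp <- matrix(0, n_prey, n_cond)
  nW <- sum(wt_cols)
  withr::with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      filled <- lg
      if (nrow(na_idx))
        filled[na_idx] <- rnorm(nrow(na_idx), model$mu[na_idx[, 1]],
                                model$sd[na_idx[, 1]])
      mW <- rowMeans(filled[, wt_cols, drop = FALSE])
      vW <- row_vars(filled[, wt_cols, drop = FALSE])
      for (ci in seq_len(n_cond)) {
        cols <- ost[ann$ligand[ost] == conds$ligand[ci] &
                      ann$time[ost] == conds$time[ci]]
        nO <- length(cols)
        mO <- rowMeans(filled[, cols, drop = FALSE])
        vO <- row_vars(filled[, cols, drop = FALSE])
        se2 <- vO / nO + vW / nW
        tstat <- (mO - mW) / sqrt(se2)
        df <- se2^2 / ((vO / nO)^2 / (nO - 1) + (vW / nW)^2 / (nW - 1))
        p <- 2 * pt(-abs(tstat), df)
        p[!is.finite(p)] <- 1
        sum_fc[, ci] <- sum_fc[, ci] + (mO - mW)
        sum_logp[, ci] <- sum_logp[, ci] + log(pmax(p, 1e-300))
      }
    }
  })
  out <- data.frame(
    prey_id = rep(preys, n_cond),
    ligand = rep(conds$ligand, each = n_prey),
    time = rep(conds$time, each = n_prey),
    log2fc = as.vector(sum_fc / n_repeats),
    p = as.vector(exp(sum_logp / n_repeats)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Volcano-asymmetry false discovery rate
#'
#' Estimates a per-candidate FDR from the asymmetry of the volcano plot:
#' for a candidate with positive log2 fold change `f` and p-value `p`,
#' the raw estimate is the number of mirror points (`log2FC <= -f`,
#' `p' <= p`) divided by the number of target points (`log2FC >= f`,
#' `p' <= p`), capped at 1. Candidates with non-positive fold change
#' receive FDR 1. Raw estimates are monotonized with a running minimum
#' along decreasing stringency (stringency ordered by target count), so
#' the final FDR is non-increasing with increasing stringency.
#'
#' @param tests data.frame with `log2fc` and `p` columns (all conditions
#'   pooled into one volcano).
#' @return `tests` with an `fdr` column appended.
#' @export
asymmetry_fdr <- function(tests) {
  f <- tests$log2fc
  p <- tests$p
  n <- length(f)
  fdr <- rep(1, n)
  pos <- which(f > 0)
  if (length(pos)) {
    targets <- integer(length(pos))
    raw <- numeric(length(pos))
    for (i in seq_along(pos)) {
      j <- pos[i]
      tgt <- sum(f >= f[j] & p <= p[j])
      dec <- sum(f <= -f[j] & p <= p[j])
      targets[i] <- tgt
      raw[i] <- min(1, dec / max(1, tgt))
    }
    # monotonize (q-value style): the FDR at a stringency level is the
    # minimum raw estimate over all levels at most as stringent, so equal
    # stringency (equal target count) always maps to one value
    ord <- order(targets, decreasing = TRUE)
    cm <- cummin(raw[ord])
    tg <- targets[ord]
    level_val <- vapply(split(seq_along(tg), tg),
                        function(ix) cm[max(ix)], numeric(1))
    fdr[pos] <- level_val[as.character(targets)]
  }
  tests$fdr <- fdr
  tests
}

#' Call specific interactors
#'
#' A prey is a specific interactor when at least one condition shows a
#' linear fold change of at least `fc_min` together with an FDR of at
#' most `fdr_max`; the flag applies prey-wide.
#'
#' @param tests data.frame from [asymmetry_fdr()] (columns `prey_id`,
#'   `log2fc`, `fdr`).
#' @param fc_min linear fold-change threshold, default 10.
#' @param fdr_max FDR threshold, default 0.05.
#' @return `tests` with an `interactor` column appended (per-row flag of
#'   the prey-wide call).
#' @export
call_interactors <- function(tests, fc_min = 10, fdr_max = 0.05) {
  hit <- 2^tests$log2fc >= fc_min & tests$fdr <= fdr_max
  hit_prey <- unique(tests$prey_id[hit])
  tests$interactor <- tests$prey_id %in% hit_prey
  tests
}

#' Interaction stoichiometry per prey and condition
#'
#' For each condition, the absolute abundance proxy of protein `x` is its
#' background-subtracted mean OST intensity (background = the prey's mean
#' WT intensity pooled over all conditions, floored at 0) divided by its
#' theoretical peptide count (iBAQ-style). The interaction stoichiometry
#' is the prey-to-bait ratio of these abundances. Display values are
#' row-max normalized to `[0, 1]`, and a hierarchical-clustering row
#' order on the normalized profiles is attached for dot-plot display.
#'
#' @param pg a cleaned, normalized [protein_groups()] table (technical
#'   replicates averaged) containing the bait row.
#' @param bait_id prey id of the bait protein.
#' @param prey_ids preys to report (default: all except the bait).
#' @return data.frame with one row per prey x condition: `prey_id`,
#'   `ligand`, `time`, `stoichiometry`, `display_value`; attribute
#'   `row_order` gives the display ordering of prey ids.
#' @export
interaction_stoichiometry <- function(pg, bait_id,
                                      prey_ids = setdiff(pg$preys$prey_id,
                                                         bait_id)) {
  if (!bait_id %in% pg$preys$prey_id) stop("bait not found: ", bait_id)
  ann <- pg$samples
  wt_cols <- ann$genotype == "WT"
  bg <- rowMeans(pg$intensity[, wt_cols, drop = FALSE], na.rm = TRUE)
  bg[is.nan(bg)] <- 0
  ost <- which(ann$genotype == "OST")
  conds <- unique(ann[ost, c("ligand", "time")])
  npep <- setNames(pg$preys$n_peptides, pg$preys$prey_id)
  rows <- match(c(bait_id, prey_ids), pg$preys$prey_id)
  if (anyNA(rows)) stop("unknown prey id(s)")
  st <- matrix(NA_real_, length(rows), nrow(conds),
               dimnames = list(c(bait_id, prey_ids),
                               paste(conds$ligand, conds$time, sep = "_")))
  for (ci in seq_len(nrow(conds))) {
    cols <- ost[ann$ligand[ost] == conds$ligand[ci] &
                  ann$time[ost] == conds$time[ci]]
    mI <- rowMeans(pg$intensity[rows, cols, drop = FALSE], na.rm = TRUE)
    mI[is.nan(mI)] <- 0
    abund <- pmax(0, mI - bg[rows]) / npep[c(bait_id, prey_ids)]
    if (!is.finite(abund[1]) || abund[1] <= 0) {
      warning("bait abundance not positive in condition ",
              colnames(st)[ci], "; stoichiometry undefined there")
      next
    }
    st[, ci] <- abund / abund[1]
  }
  prey_st <- st[-1, , drop = FALSE]
  row_max <- apply(prey_st, 1, max, na.rm = TRUE)
  row_max[!is.finite(row_max) | row_max <= 0] <- NA_real_
  disp <- prey_st / row_max
  ord <- rownames(prey_st)
  cl_rows <- which(!is.na(row_max))
  if (length(cl_rows) > 2) {
    d0 <- disp[cl_rows, , drop = FALSE]
    d0[is.na(d0)] <- 0
    hc <- hclust(dist(d0), method = "average")
    ord <- c(rownames(prey_st)[cl_rows][hc$order],
             rownames(prey_st)[-cl_rows])
  }
  out <- data.frame(
    prey_id = rep(rownames(prey_st), ncol(prey_st)),
    ligand = rep(conds$ligand, each = nrow(prey_st)),
    time = rep(conds$time, each = nrow(prey_st)),
    stoichiometry = as.vector(prey_st),
    display_value = as.vector(disp),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "row_order") <- ord
  out
}

#' Discrimination score of an interaction's stoichiometry kinetics
#'
#' Converts a prey's per-condition stoichiometries into log2 fold changes
#' relative to the mean unstimulated stoichiometry and delegates to the
#' phospho-site discrimination machinery (sign alignment, trapezoidal
#' AUC, average loss). Non-positive stoichiometries are floored at half
#' the smallest positive stoichiometry of the prey before taking logs.
#'
#' @param stoich data.frame for a single prey with `ligand`, `time` and
#'   `stoichiometry` columns, including an `unstim` row.
#' @param times time grid (seconds) of the AP-MS design.
#' @return one-row data.frame: `auc_g4`, `auc_t4`, `auc_n4`, `loss_g4`,
#'   `loss_t4`, `score`, `class`.
#' @export
stoichiometry_discrimination <- function(stoich, times = c(0, 30, 120, 300)) {
  s0 <- mean(stoich$stoichiometry[stoich$ligand == "unstim"], na.rm = TRUE)
  if (!is.finite(s0) || s0 <= 0)
    stop("no positive unstimulated stoichiometry")
  pos <- stoich$stoichiometry[!is.na(stoich$stoichiometry) &
                                stoich$stoichiometry > 0]
  floor_val <- min(pos) / 2
  profile_of <- function(lig) {
    vapply(times, function(t) {
      if (t == 0) return(0)
      v <- stoich$stoichiometry[stoich$ligand == lig & stoich$time == t]
      v <- mean(v, na.rm = TRUE)
      if (!is.finite(v)) return(NA_real_)
      log2(max(v, floor_val) / s0)
    }, numeric(1))
  }
  profiles <- list(N4 = matrix(profile_of("N4"), 1),
                   T4 = matrix(profile_of("T4"), 1),
                   G4 = matrix(profile_of("G4"), 1))
  al <- align_profiles(profiles, times)
  auc <- lapply(al$profiles, response_auc, times = times)
  ds <- discrimination_score(auc$G4, auc$T4, auc$N4)
  data.frame(auc_g4 = auc$G4, auc_t4 = auc$T4, auc_n4 = auc$N4,
             loss_g4 = ds$loss_g4, loss_t4 = ds$loss_t4, score = ds$score,
             class = classify_response(ds$score), stringsAsFactors = FALSE)
}
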