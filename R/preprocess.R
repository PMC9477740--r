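#' Correct TMT channel mixing errors
#'
#' Divides each channel by its total non-modified (non-phosphorylated)
#' signal relative to the median channel total, so that the median channel
#' is left unchanged. The channel totals come from the unenriched aliquot
#' of each TMT mix.
#'
#' @param raw numeric matrix of linear-scale intensities, sites x channels
#'   (one TMT batch).
#' @param channel_totals strictly positive numeric vector, one total per
#'   column of `raw`.
#' @return corrected matrix of the same shape.
#' @export
correct_mixing <- function(raw, channel_totals) {
  stopifnot(is.matrix(raw) || is.data.frame(raw))
  raw <- as.matrix(raw)
  if (length(channel_totals) != ncol(raw))
    stop("need one channel total per column")
  bad <- which(!(channel_totals > 0))
  if (length(bad))
    stop("non-positive channel total for channel(s): ",
         paste(bad, collapse = ", "))
  factors <- channel_totals / median(channel_totals)
  sweep(raw, 2, factors, "/")
}

#' Filter sites on phospho-localization confidence
#'
#' Keeps a site when its maximum localization score over replicates is at
#' least `threshold` (boundary inclusive).
#'
#' @param sites data.frame of site records with one or more
#'   `loc_score_rep<k>` columns (values in `[0, 100]`).
#' @param threshold percent cutoff, default 75.
#' @return the retained rows of `sites`.
#' @export
filter_localization <- function(sites, threshold = 75) {
  stopifnot(threshold >= 0, threshold <= 100)
  loc_cols <- grep("^loc_score_rep", names(sites), value = TRUE)
  if (!length(loc_cols)) stop("no localization-score columns found")
  best <- do.call(pmax, c(unname(sites[loc_cols]), list(na.rm = TRUE)))
  sites[!is.na(best) & best >= threshold, , drop = FALSE]
}

#' Partition sites between the TiO2 and pY-IP fractions
#'
#' Enforces the fraction logic of the two enrichment routes: the pY-IP
#' fraction retains only tyrosine sites, and a tyrosine site quantified in
#' the pY-IP is removed from the TiO2 fraction (so no site is duplicated
#' across fractions). Idempotent.
#'
#' @param sites data.frame with `site_id`, `residue` (`S`/`T`/`Y`) and
#'   `fraction` (`TiO2` or `pY-IP`) columns.
#' @return the retained rows of `sites`.
#' @export
partition_fractions <- function(sites) {
  stopifnot(all(c("site_id", "residue", "fraction") %in% names(sites)))
  py <- sites$fraction == "pY-IP" & sites$residue == "Y"
  py_ids <- sites$site_id[py]
  tio_keep <- sites$fraction == "TiO2" &
    !(sites$residue == "Y" & sites$site_id %in% py_ids)
  sites[py | tio_keep, , drop = FALSE]
}

#' Average log2 intensities over technical replicates
#'
#' Collapses columns that differ only in their technical-replicate index
#' to their arithmetic mean over observed values (on the log2 scale); a
#' cell stays missing only when all technical replicates are missing.
#'
#' @param pset a [phospho_set()] (log2 scale).
#' @return a [phospho_set()] with one column per biological replicate.
#' @export
average_technical_replicates <- function(pset) {
  ann <- pset$samples
  key <- paste(ann$batch, ann$channel, ann$ligand, ann$time, ann$biorep,
               sep = ".")
  groups <- split(seq_len(ncol(pset$log2)), factor(key, levels = unique(key)))
  n <- nrow(pset$log2)
  vals <- vapply(groups, function(cols)
    rowMeans(pset$log2[, cols, drop = FALSE], na.rm = TRUE), numeric(n))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = n)
  vals[is.nan(vals)] <- NA_real_
  obs <- vapply(groups, function(cols)
    rowSums(pset$observed[, cols, drop = FALSE]) > 0, logical(n))
  if (!is.matrix(obs)) obs <- matrix(obs, nrow = n)
  new_ann <- ann[!duplicated(key), , drop = FALSE]
  new_ann$techrep <- 1L
  rownames(new_ann) <- NULL
  colnames(vals) <- colnames(obs) <- names(groups)
  phospho_set(as.matrix(vals), new_ann, pset$sites, as.matrix(obs))
}

#' Impute fully missing conditions with low-intensity draws
#'
#' For each site and each (ligand, time) condition with zero observed
#' replicates, fills all of that condition's cells with independent draws
#' from a Gaussian whose mean is the 5% quantile and whose s.d. is the
#' s.d. of all observed log2 values in the data set. Conditions with at
#' least one observed replicate are untouched, as are all observed cells.
#'
#' @param pset a [phospho_set()] (log2 scale, technical replicates already
#'   averaged).
#' @param seed optional integer seed for the imputation draws.
#' @return a [phospho_set()] whose imputed cells carry
#'   `observed = FALSE` but a non-missing value.
#' @export
impute_condition_missing <- function(pset, seed = NULL) {
  vals <- pset$log2
  obs_vals <- vals[pset$observed]
  if (!length(obs_vals)) stop("no observed values: cannot define the imputation model")
  q05 <- unname(quantile(obs_vals, 0.05, na.rm = TRUE))
  sd_all <- sd(obs_vals, na.rm = TRUE)
  key <- condition_key(pset$samples)
  draw <- function() {
    for (k in unique(key)) {
      cols <- which(key == k)
      sub_obs <- pset$observed[, cols, drop = FALSE]
      rows <- which(rowSums(sub_obs) == 0)
      if (length(rows)) {
        vals[rows, cols] <<- rnorm(length(rows) * length(cols), q05, sd_all)
      }
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  phospho_set(vals, pset$samples, pset$sites, pset$observed)
}

#' Normalize batches on shared conditions
#'
#' Per site, shifts each batch by the difference between that batch's mean
#' over the shared conditions (unstimulated and N4, present in every
#' batch) and the site's grand mean over all batches' shared-condition
#' cells. After normalization the per-site batch means over shared
#' conditions coincide; within-batch differences between columns are
#' unchanged (shift-only).
#'
#' @param pset a [phospho_set()] (log2 scale, imputation done).
#' @return the normalized [phospho_set()].
#' @export
normalize_batches <- function(pset) {
  vals <- pset$log2
  shared <- pset$samples$ligand %in% c("unstim", "N4")
  if (!any(shared)) stop("no shared (unstim/N4) conditions present")
  batches <- unique(pset$samples$batch)
  if (length(batches) == 1L) return(pset)
  shared_vals <- vals[, shared, drop = FALSE]
  grand <- rowMeans(shared_vals, na.rm = TRUE)
  n_skipped <- 0L
  for (b in batches) {
    in_b <- pset$samples$batch == b
    sb <- vals[, in_b & shared, drop = FALSE]
    offset <- rowMeans(sb, na.rm = TRUE) - grand
    none <- !is.finite(offset)
    n_skipped <- n_skipped + sum(none)
    offset[none] <- 0
    vals[, in_b] <- vals[, in_b, drop = FALSE] - offset
  }
  if (n_skipped > 0)
    message(sprintf("normalize_batches: %d (site, batch) pairs had no shared-condition observations; offset 0 used", n_skipped))
  phospho_set(vals, pset$samples, pset$sites, pset$observed)
}

#' Pairwise Pearson correlation between samples
#'
#' Pearson correlation over pairwise-complete observations; constant
#' columns yield missing correlations; the diagonal is 1.
#'
#' @param x a [phospho_set()] or a numeric matrix (variables in columns).
#' @return symmetric correlation matrix.
#' @export
sample_correlation <- function(x) {
  mat <- if (inherits(x, "phospho_set")) x$log2 else as.matrix(x)
  r <- suppressWarnings(cor(mat, use = "pairwise.complete.obs",
                            method = "pearson"))
  diag(r) <- 1
  r
}

#' Preprocess a simulated or imported phospho data set
#'
#' Runs the standard preprocessing chain: per-batch mixing correction
#' (when channel totals are available), localization filtering, fraction
#' partitioning, log2 transform (zero raw intensities treated as
#' missing), technical-replicate averaging, low-quantile imputation of
#' fully missing conditions, and between-batch normalization.
#'
#' @param sim a `phospho_sim` (from [simulate_phospho_dataset()]) or a
#'   list with elements `intensity`, `samples`, `sites` and optionally
#'   `channel_totals`.
#' @param localization_threshold localization cutoff, default 75.
#' @param imputation_seed seed for [impute_condition_missing()].
#' @return a [phospho_set()] ready for the regulation and discrimination
#'   analyses.
#' @export
preprocess_phospho <- function(sim, localization_threshold = 75,
                               imputation_seed = 1L) {
  intens <- sim$intensity
  if (!nrow(intens)) stop("no sites in the input table")
  ann <- sim$samples
  if (!is.null(sim$channel_totals)) {
    for (b in unique(ann$batch)) {
      cols <- which(ann$batch == b)
      totals <- sim$channel_totals[b, ann$channel[cols]]
      intens[, cols] <- correct_mixing(intens[, cols, drop = FALSE], totals)
    }
  }
  sites <- filter_localization(sim$sites, localization_threshold)
  sites <- partition_fractions(sites)
  keep <- match(sites$site_id, sim$sites$site_id)
  intens <- intens[keep, , drop = FALSE]
  intens[!is.na(intens) & intens <= 0] <- NA_real_
  lg <- log2(intens)
  pset <- phospho_set(lg, ann, sites)
  pset <- average_technical_replicates(pset)
  pset <- impute_condition_missing(pset, seed = imputation_seed)
  normalize_batches(pset)
}
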