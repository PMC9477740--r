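#' Site-level phospho-intensity container
#'
#' Bundles a sites x samples log2 intensity matrix with its sample
#' annotation, site annotation, and a per-cell `observed` mask. Cells that
#' are non-missing but not observed were imputed.
#'
#' @param log2_intensity numeric matrix, sites in rows, samples in columns
#'   (`NA` = missing). Rownames are site ids, colnames sample ids.
#' @param samples data.frame with one row per column of `log2_intensity`;
#'   must contain `batch`, `channel`, `ligand` (one of `unstim`, `N4`,
#'   `T4`, `G4`), `time` (seconds, 0 for `unstim`), `biorep`, `techrep`.
#' @param sites data.frame with one row per row of `log2_intensity`; must
#'   contain `site_id`, and typically `protein_id`, `residue`, `position`,
#'   `fraction` and localization-score columns `loc_score_rep<k>`.
#' @param observed logical matrix of the same shape; defaults to
#'   `!is.na(log2_intensity)`.
#' @return An object of class `phospho_set`.
#' @export
phospho_set <- function(log2_intensity, samples, sites,
                        observed = !is.na(log2_intensity)) {
  stopifnot(is.matrix(log2_intensity),
            nrow(samples) == ncol(log2_intensity),
            nrow(sites) == nrow(log2_intensity),
            identical(dim(observed), dim(log2_intensity)))
  needed <- c("batch", "channel", "ligand", "time", "biorep", "techrep")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols))
    stop("sample annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"site_id" %in% names(sites)) stop("site annotation lacks 'site_id'")
  bad <- xor(samples$ligand == "unstim", samples$time == 0)
  if (any(bad)) stop("ligand 'unstim' must coincide with time 0")
  rownames(log2_intensity) <- sites$site_id
  structure(list(log2 = log2_intensity, samples = samples, sites = sites,
                 observed = observed),
            class = "phospho_set")
}

#' @export
print.phospho_set <- function(x, ...) {
  cat(sprintf("phospho_set: %d sites x %d samples\n", nrow(x$log2), ncol(x$log2)))
  cat(sprintf("  observed cells: %d, imputed: %d, missing: %d\n",
              sum(x$observed), sum(!x$observed & !is.na(x$log2)),
              sum(is.na(x$log2))))
  cat("  ligands:", paste(sort(unique(x$samples$ligand)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.phospho_set <- function(x) dim(x$log2)

# subset sites, keeping annotation in register
subset_sites <- function(pset, keep) {
  phospho_set(pset$log2[keep, , drop = FALSE],
              pset$samples,
              pset$sites[keep, , drop = FALSE],
              pset$observed[keep, , drop = FALSE])
}

#' Site ids quantified in every condition
#'
#' A site is complete when it has at least one observed (non-imputed)
#' value in every (ligand, time) condition present in the annotation.
#' Mirrors the restriction of discrimination scoring to sites quantified
#' across all ligands and stimulation times.
#'
#' @param pset a [phospho_set()].
#' @return character vector of site ids.
#' @export
quantified_complete <- function(pset) {
  key <- condition_key(pset$samples)
  ok <- rep(TRUE, nrow(pset$log2))
  for (k in unique(key)) {
    cols <- key == k
    ok <- ok & rowSums(pset$observed[, cols, drop = FALSE]) >= 1
  }
  pset$sites$site_id[ok]
}
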