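#' Detection filter for per-ligand statistics
#'
#' A site is eligible for a ligand's regulation test when at least three
#' of that ligand's conditions (time points, the unstimulated baseline
#' counting as one) each carry at least two observed (non-imputed)
#' quantification values.
#'
#' @param pset a [phospho_set()].
#' @param ligand one of `"N4"`, `"T4"`, `"G4"`.
#' @param min_conditions minimum number of qualifying time points (3).
#' @param min_values minimum observed values per qualifying time point (2).
#' @return character vector of eligible site ids.
#' @export
detection_filter <- function(pset, ligand, min_conditions = 3, min_values = 2) {
  ann <- pset$samples
  use <- ann$ligand %in% c(ligand, "unstim")
  times <- sort(unique(ann$time[use]))
  n_ok <- matrix(0L, nrow(pset$log2), length(times))
  for (i in seq_along(times)) {
    cols <- use & ann$time == times[i]
    n_ok[, i] <- rowSums(pset$observed[, cols, drop = FALSE])
  }
  eligible <- rowSums(n_ok >= min_values) >= min_conditions
  pset$sites$site_id[eligible]
}

#' One-way ANOVA with Tukey HSD pairwise contrasts
#'
#' Tests whether a site's log2 intensity differs across time groups, and
#' reports every pairwise time contrast with its Tukey-corrected p-value
#' and log2 fold change (difference of group means).
#'
#' Degenerate inputs are resolved explicitly: identical values everywhere
#' give `anova_p = 1`; zero within-group variance with unequal means gives
#' the limiting `anova_p = 0`.
#'
#' @param values numeric vector of log2 intensities.
#' @param groups factor (or coercible) of time labels, same length.
#' @return list with `anova_p` and `pairwise`, a data.frame with columns
#'   `group_a`, `group_b`, `log2fc` (`mean_b - mean_a`) and `corrected_p`.
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  keep <- !is.na(values)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("need at least two observations per group")

  means <- tapply(values, groups, mean)
  combs <- utils::combn(levels(groups), 2)
  pair_df <- data.frame(group_a = combs[1, ], group_b = combs[2, ],
                        log2fc = means[combs[2, ]] - means[combs[1, ]],
                        row.names = NULL, stringsAsFactors = FALSE)

  within_var <- tapply(values, groups, var)
  if (all(within_var < .Machine$double.eps)) {
    if (max(means) - min(means) < 1e-12) {
      pair_df$corrected_p <- 1
      return(list(anova_p = 1, pairwise = pair_df))
    }
    pair_df$corrected_p <- ifelse(abs(pair_df$log2fc) < 1e-12, 1, 0)
    return(list(anova_p = 0, pairwise = pair_df))
  }

  dat <- data.frame(y = values, g = groups)
  fit <- aov(y ~ g, data = dat)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  if (is.nan(anova_p)) anova_p <- 1
  tk <- TukeyHSD(fit)$g
  key <- paste(pair_df$group_b, pair_df$group_a, sep = "-")
  pair_df$corrected_p <- tk[key, "p adj"]
  list(anova_p = unname(anova_p), pairwise = pair_df)
}

#' Regulation call from ANOVA and pairwise results
#'
#' A site is regulated for a ligand when the ANOVA p-value is at most
#' `p_threshold` and at least one pair of time points has a corrected
#' p-value at most `p_threshold` together with an absolute linear fold
#' change of at least `fc_threshold` (i.e. `|log2FC| >= log2(fc_threshold)`).
#'
#' @param anova_p ANOVA p-value.
#' @param pairwise pairwise table from [anova_tukey()].
#' @param fc_threshold linear fold-change threshold (1.5).
#' @param p_threshold significance threshold (0.05).
#' @return logical flag.
#' @export
call_regulated <- function(anova_p, pairwise, fc_threshold = 1.5,
                           p_threshold = 0.05) {
  if (is.na(anova_p) || anova_p > p_threshold) return(FALSE)
  hit <- pairwise$corrected_p <= p_threshold &
    abs(pairwise$log2fc) >= log2(fc_threshold)
  any(hit, na.rm = TRUE)
}

#' Per-ligand regulation analysis
#'
#' Applies the detection filter, runs the ANOVA/Tukey test per eligible
#' site over the ligand's time groups (the unstimulated baseline included
#' as the `t = 0` level; imputed values participate in the test), and
#' flags regulated sites.
#'
#' @param pset a [phospho_set()] after preprocessing.
#' @param ligands ligands to test.
#' @param fc_threshold,p_threshold thresholds of [call_regulated()].
#' @return data.frame with one row per (site, ligand): `site_id`,
#'   `ligand`, `anova_p`, `best_pair`, `best_pair_p`, `best_pair_log2fc`,
#'   `regulated`. The best pair is the significant pair with the largest
#'   absolute fold change (or the smallest p-value when none is
#'   significant).
#' @export
test_regulation <- function(pset, ligands = c("N4", "T4", "G4"),
                            fc_threshold = 1.5, p_threshold = 0.05) {
  out <- list()
  for (lig in intersect(ligands, unique(pset$samples$ligand))) {
    ids <- detection_filter(pset, lig)
    use_cols <- pset$samples$ligand %in% c(lig, "unstim")
    tt <- pset$samples$time[use_cols]
    times <- factor(tt, levels = sort(unique(tt)))
    rows <- match(ids, pset$sites$site_id)
    res <- lapply(rows, function(i) {
      y <- pset$log2[i, use_cols]
      # time groups with fewer than two quantified values cannot enter the
      # ANOVA; the detection filter guarantees at least three that can
      n_by_group <- tapply(!is.na(y), times, sum)
      ok_groups <- names(n_by_group)[!is.na(n_by_group) & n_by_group >= 2]
      use <- !is.na(y) & as.character(times) %in% ok_groups
      at <- anova_tukey(y[use], droplevels(times[use]))
      sig <- at$pairwise$corrected_p <= p_threshold &
        abs(at$pairwise$log2fc) >= log2(fc_threshold)
      best <- if (any(sig, na.rm = TRUE)) {
        cand <- which(sig)
        cand[which.max(abs(at$pairwise$log2fc[cand]))]
      } else which.min(at$pairwise$corrected_p)
      data.frame(
        site_id = pset$sites$site_id[i], ligand = lig,
        anova_p = at$anova_p,
        best_pair = paste(at$pairwise$group_a[best],
                          at$pairwise$group_b[best], sep = "-"),
        best_pair_p = at$pairwise$corrected_p[best],
        best_pair_log2fc = at$pairwise$log2fc[best],
        regulated = call_regulated(at$anova_p, at$pairwise, fc_threshold,
                                   p_threshold),
        stringsAsFactors = FALSE)
    })
    out[[lig]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap summary of per-ligand regulated sets
#'
#' @param regulated_sets named list of site-id vectors (one per ligand).
#' @return list with `counts` (per-ligand set sizes), `intersections`
#'   (data.frame of all pairwise and higher-order intersection sizes) and
#'   `directional_pct` (matrix, entry `[a, b]` = `100 * |A n B| / |A|`).
#' @export
overlap_summary <- function(regulated_sets) {
  sets <- lapply(regulated_sets, unique)
  nm <- names(sets)
  counts <- vapply(sets, length, integer(1))
  combos <- list()
  if (length(sets) >= 2) {
    for (k in 2:length(sets)) {
      cc <- utils::combn(nm, k, simplify = FALSE)
      for (grp in cc) {
        inter <- Reduce(intersect, sets[grp])
        combos[[paste(grp, collapse = "&")]] <- length(inter)
      }
    }
  }
  intersections <- data.frame(
    sets = if (length(combos)) names(combos) else character(0),
    size = if (length(combos)) unlist(combos, use.names = FALSE) else integer(0),
    stringsAsFactors = FALSE)
  pct <- matrix(NA_real_, length(sets), length(sets), dimnames = list(nm, nm))
  for (a in nm) for (b in nm) {
    pct[a, b] <- if (length(sets[[a]]) == 0) NA_real_
                 else 100 * length(intersect(sets[[a]], sets[[b]])) /
                      length(sets[[a]])
  }
  list(counts = counts, intersections = intersections, directional_pct = pct)
}
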