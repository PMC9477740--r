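#' Fold-change kinetics relative to the unstimulated baseline
#'
#' For each site, the log2 fold change at time `t` is the mean log2
#' intensity over the ligand's replicates at `t` minus the mean over the
#' unstimulated replicates; `log2FC(0) = 0` by construction. Imputed
#' values participate in the means.
#'
#' @param pset a [phospho_set()] after preprocessing.
#' @param ligand one of `"N4"`, `"T4"`, `"G4"`.
#' @param times time grid (seconds); the first entry must be 0.
#' @return matrix, sites x times, of log2 fold changes.
#' @export
fold_change_kinetics <- function(pset, ligand,
                                 times = c(0, 30, 120, 300, 600)) {
  stopifnot(times[1] == 0)
  ann <- pset$samples
  unstim <- ann$ligand == "unstim"
  if (!any(unstim)) stop("no unstimulated samples present")
  m0 <- rowMeans(pset$log2[, unstim, drop = FALSE], na.rm = TRUE)
  if (any(is.nan(m0))) stop("site(s) without any unstimulated value")
  out <- matrix(0, nrow(pset$log2), length(times),
                dimnames = list(pset$sites$site_id, times))
  for (i in seq_along(times)[-1]) {
    cols <- ann$ligand == ligand & ann$time == times[i]
    if (!any(cols)) stop("no samples for ", ligand, " at t = ", times[i])
    mt <- rowMeans(pset$log2[, cols, drop = FALSE], na.rm = TRUE)
    out[, i] <- mt - m0
  }
  out
}

#' Trapezoidal area under a response profile
#'
#' Integrates a (sign-aligned) log2 fold-change profile over the sampled
#' time grid by the trapezoid rule. Units: log2FC x seconds.
#'
#' @param profile numeric vector over `times`, or a matrix with one
#'   profile per row.
#' @param times time grid in seconds.
#' @return numeric AUC (one value per profile).
#' @export
response_auc <- function(profile, times = c(0, 30, 120, 300, 600)) {
  if (is.matrix(profile)) {
    stopifnot(ncol(profile) == length(times))
    return(apply(profile, 1, function(p) pracma::trapz(times, p)))
  }
  stopifnot(length(profile) == length(times))
  pracma::trapz(times, profile)
}

#' Sign-align response profiles on the N4 response
#'
#' Multiplies every ligand's profile of a site by the sign of that site's
#' N4 AUC, so that down-regulated sites yield a positive N4 AUC and
#' comparable losses. Sites with a zero N4 AUC keep sign +1.
#'
#' @param profiles named list of matrices (sites x times), one per
#'   ligand; must contain `N4`.
#' @param times time grid in seconds.
#' @return list with `profiles` (aligned) and `sign` (per-site factor).
#' @export
align_profiles <- function(profiles, times = c(0, 30, 120, 300, 600)) {
  stopifnot("N4" %in% names(profiles))
  s <- sign(response_auc(profiles$N4, times))
  s[s == 0] <- 1
  list(profiles = lapply(profiles, function(p) p * s), sign = s)
}

#' Discrimination score from per-ligand AUCs
#'
#' The response loss of a weak ligand is `100 * (1 - AUC_w / AUC_N4)`,
#' clipped to `[0, 100]`; the discrimination score is the mean of the
#' available losses. 0% marks an affinity-independent response, 100% an
#' N4-only response. The score is undefined (`NA`) when the N4 AUC is not
#' positive (site not N4-responsive).
#'
#' @param auc_g4,auc_t4,auc_n4 per-ligand AUCs (vectorized). Either weak
#'   ligand may be `NA`; at least one must be available per site.
#' @return data.frame with `loss_g4`, `loss_t4` and `score` (percent).
#' @export
discrimination_score <- function(auc_g4, auc_t4, auc_n4) {
  n <- max(length(auc_g4), length(auc_t4), length(auc_n4))
  auc_g4 <- rep_len(auc_g4, n); auc_t4 <- rep_len(auc_t4, n)
  auc_n4 <- rep_len(auc_n4, n)
  ok <- !is.na(auc_n4) & auc_n4 > 0
  loss <- function(a) ifelse(ok & !is.na(a), clip(100 * (1 - a / auc_n4), 0, 100),
                             NA_real_)
  loss_g4 <- loss(auc_g4)
  loss_t4 <- loss(auc_t4)
  score <- rowMeans(cbind(loss_g4, loss_t4), na.rm = TRUE)
  score[is.nan(score) | !ok] <- NA_real_
  data.frame(loss_g4 = loss_g4, loss_t4 = loss_t4, score = score)
}

#' Response class from the discrimination score
#'
#' Unaffected: score <= 40; Gradual: 40 < score <= 80; Digital:
#' score > 80 (boundaries inclusive on the lower class).
#'
#' @param score discrimination score in `[0, 100]` (vectorized; `NA`
#'   yields `NA`).
#' @param bounds the two class boundaries, default `c(40, 80)`.
#' @return character vector of classes.
#' @export
classify_response <- function(score, bounds = c(40, 80)) {
  ifelse(is.na(score), NA_character_,
         ifelse(score <= bounds[1], "Unaffected",
                ifelse(score <= bounds[2], "Gradual", "Digital")))
}

#' Score sites: AUCs, losses, discrimination score and class
#'
#' Computes per-ligand fold-change kinetics, sign-aligns them on the N4
#' response, integrates the AUCs and derives losses, score and class per
#' site.
#'
#' @param pset a [phospho_set()] after preprocessing.
#' @param site_ids sites to score (default: sites quantified in every
#'   condition, see [quantified_complete()]).
#' @param times time grid in seconds.
#' @param bounds class boundaries for [classify_response()].
#' @return data.frame: `site_id`, `auc_g4`, `auc_t4`, `auc_n4`,
#'   `loss_g4`, `loss_t4`, `score`, `class`.
#' @export
score_sites <- function(pset, site_ids = quantified_complete(pset),
                        times = c(0, 30, 120, 300, 600),
                        bounds = c(40, 80)) {
  pset <- subset_sites(pset, pset$sites$site_id %in% site_ids)
  profiles <- list(N4 = fold_change_kinetics(pset, "N4", times),
                   T4 = fold_change_kinetics(pset, "T4", times),
                   G4 = fold_change_kinetics(pset, "G4", times))
  al <- align_profiles(profiles, times)
  auc <- lapply(al$profiles, response_auc, times = times)
  ds <- discrimination_score(auc$G4, auc$T4, auc$N4)
  data.frame(site_id = pset$sites$site_id,
             auc_g4 = auc$G4, auc_t4 = auc$T4, auc_n4 = auc$N4,
             loss_g4 = ds$loss_g4, loss_t4 = ds$loss_t4, score = ds$score,
             class = classify_response(ds$score, bounds),
             stringsAsFactors = FALSE)
}

#' Partition scored sites into kinetic groups
#'
#' Within each response class, clusters the per-site s.d.-scaled N4
#' log2 fold-change profiles into up to `n_clusters` kinetic clusters
#' (hierarchical clustering, Euclidean distance, average linkage),
#' yielding up to `3 x n_clusters` groups. Sites are processed in
#' lexicographic site-id order so the partition is order-independent.
#'
#' @param n4_profiles matrix of N4 log2 fold changes, sites x times, with
#'   site ids as rownames.
#' @param classes character vector of classes, aligned with the rows.
#' @param n_clusters kinetic clusters per class, default 4.
#' @return data.frame: `site_id`, `class`, `cluster`, `group_id`.
#' @export
partition_groups <- function(n4_profiles, classes, n_clusters = 4) {
  stopifnot(nrow(n4_profiles) == length(classes))
  ord <- order(rownames(n4_profiles))
  n4_profiles <- n4_profiles[ord, , drop = FALSE]
  classes <- classes[ord]
  class_levels <- c("Unaffected", "Gradual", "Digital")
  out <- list()
  for (ci in seq_along(class_levels)) {
    cl <- class_levels[ci]
    rows <- which(!is.na(classes) & classes == cl)
    if (!length(rows)) next
    x <- n4_profiles[rows, , drop = FALSE]
    s <- apply(x, 1, sd)
    xs <- x / ifelse(s > 0, s, 1)
    n_distinct <- nrow(unique(round(xs, 10)))
    k <- min(n_clusters, n_distinct)
    if (k < n_clusters)
      message(sprintf("partition_groups: class %s has %d distinct profile(s); using %d cluster(s)",
                      cl, n_distinct, k))
    memb <- if (nrow(xs) == 1 || k == 1) rep(1L, nrow(xs))
            else cutree(hclust(dist(xs), method = "average"), k = k)
    out[[cl]] <- data.frame(site_id = rownames(xs), class = cl,
                            cluster = as.integer(memb),
                            group_id = (ci - 1L) * n_clusters + as.integer(memb),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Kinase-substrate enrichment along the discrimination score
#'
#' Bins scored sites into non-overlapping score intervals and, for each
#' kinase x bin cell, computes the hypergeometric upper-tail probability
#' of observing at least `k` of the kinase's substrates in the bin, the
#' fold enrichment `(k/n) / (K/N)`, and a significance flag (p <= 0.05,
#' fold enrichment >= 2, and at least 2 substrates, by default).
#'
#' @param map named list, kinase to substrate site ids.
#' @param scores named numeric vector, site id to discrimination score
#'   (`NA` scores are dropped).
#' @param bin_width score bin width in percent (default 10; the first bin
#'   is `[0, 10]`, later bins are left-open).
#' @param p_threshold,fold_min,k_min significance criteria.
#' @return data.frame with one row per kinase x bin: `kinase`, `bin_lo`,
#'   `bin_hi`, `k`, `n`, `K`, `N`, `fold_enrichment`, `p`, `significant`,
#'   `depleted` (fold enrichment < 1, displayed gray).
#' @export
kinase_enrichment <- function(map, scores, bin_width = 10,
                              p_threshold = 0.05, fold_min = 2, k_min = 2) {
  scores <- scores[!is.na(scores)]
  N <- length(scores)
  if (!N) stop("no defined scores")
  breaks <- seq(0, 100, by = bin_width)
  bin <- cut(scores, breaks, include.lowest = TRUE, right = TRUE)
  out <- list()
  for (kin in names(map)) {
    subs <- intersect(map[[kin]], names(scores))
    K <- length(subs)
    for (bi in seq_len(length(breaks) - 1)) {
      in_bin <- names(scores)[as.integer(bin) == bi]
      n <- length(in_bin)
      k <- length(intersect(subs, in_bin))
      p <- if (n == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      fold <- if (n == 0 || K == 0) NA_real_ else (k / n) / (K / N)
      if (!is.na(fold) && k == 0) fold <- 0
      sig <- !is.na(fold) && p <= p_threshold && fold >= fold_min && k >= k_min
      out[[length(out) + 1]] <- data.frame(
        kinase = kin, bin_lo = breaks[bi], bin_hi = breaks[bi + 1],
        k = k, n = n, K = K, N = N, fold_enrichment = fold, p = p,
        significant = sig, depleted = !is.na(fold) && fold < 1,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
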