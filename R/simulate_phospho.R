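#' Unimodal kinetic pulse
#'
#' Gamma-shaped response pulse `(t/tp) * exp(1 - t/tp)`, rising from 0 at
#' `t = 0` to 1 at the peak time `tp` and decaying afterwards. Used as the
#' kinetic archetype of simulated phosphorylation and stoichiometry
#' responses.
#'
#' @param t time in seconds (vector).
#' @param peak_time peak time in seconds (> 0).
#' @return pulse values in `[0, 1]`.
#' @export
pulse_response <- function(t, peak_time) {
  stopifnot(all(peak_time > 0))
  n <- max(length(t), length(peak_time))
  t <- rep_len(t, n)
  x <- t / rep_len(peak_time, n)
  out <- x * exp(1 - x)
  out[t <= 0] <- 0
  out
}

#' Configuration of the phosphoproteomics simulator
#'
#' Encodes the multiplexed study design emulated by
#' [simulate_phospho_dataset()]: six 10-plex TMT batches, each carrying an
#' unstimulated channel, N4 at four stimulation times and one weak ligand
#' (T4 in batches 1-3, G4 in batches 4-6) at the same four times; the
#' spare tenth channel is left unused and is not exported. This yields six
#' biological replicates for unstimulated and each N4 time point and three
#' for each T4 and G4 time point.
#'
#' @param n_sites number of responsive sites (split across classes).
#' @param class_proportions fractions of Unaffected, Gradual and Digital
#'   sites among the `n_sites` responsive sites; must sum to 1.
#' @param n_unresponsive number of additional Null (flat-kinetics) sites.
#' @param amplitude_range interval of the peak N4 response amplitude
#'   (log2 fold change units).
#' @param peak_time_set candidate peak times (seconds), sampled per site.
#' @param noise_sd per-measurement log2-intensity noise s.d.
#' @param batch_sd s.d. of the per-(site, batch) offset removed by
#'   [normalize_batches()].
#' @param missing_rate_random probability of random dropout per cell.
#' @param missing_lod log2 intensity below which intensity-dependent
#'   dropout becomes likely (soft limit of detection).
#' @param missing_scale logistic scale of the intensity-dependent dropout.
#' @param localization_alpha,localization_beta Beta parameters of the
#'   localization-score distribution (scaled to `[0, 100]`).
#' @param n_loc_replicates number of per-site localization scores.
#' @param mixing_error_range interval of the multiplicative per-channel
#'   mixing bias.
#' @param baseline_mean,baseline_sd distribution of per-site baseline
#'   log2 intensity.
#' @param gradual_score_range interval from which the target
#'   discrimination score of Gradual sites is drawn.
#' @param gradual_spread half-distance (score points) between the G4 and
#'   T4 losses of a Gradual site (G4 loses more).
#' @param down_fraction fraction of responsive sites that are
#'   down-regulated (dephosphorylated) on stimulation.
#' @param n_technical technical replicates per sample.
#' @param seed integer seed; the generator is a pure function of the
#'   configuration including the seed.
#' @return an object of class `phospho_sim_config`.
#' @export
phospho_sim_config <- function(n_sites = 300,
                               class_proportions = c(Unaffected = 1 / 3,
                                                     Gradual = 1 / 3,
                                                     Digital = 1 / 3),
                               n_unresponsive = 60,
                               amplitude_range = c(2, 4),
                               peak_time_set = c(120, 300, 600),
                               noise_sd = 0.25,
                               batch_sd = 0.3,
                               missing_rate_random = 0.05,
                               missing_lod = 19.5,
                               missing_scale = 1,
                               localization_alpha = 8,
                               localization_beta = 0.7,
                               n_loc_replicates = 3,
                               mixing_error_range = c(0.9, 1.1),
                               baseline_mean = 22,
                               baseline_sd = 1.5,
                               gradual_score_range = c(52, 68),
                               gradual_spread = 12,
                               down_fraction = 0.15,
                               n_technical = 1,
                               seed = 1L) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (n_unresponsive < 0) stop("n_unresponsive must be >= 0")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(class_proportions < 0)) stop("class_proportions must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (missing_rate_random < 0 || missing_rate_random > 1)
    stop("missing_rate_random must be in [0, 1]")
  if (length(mixing_error_range) != 2 || any(mixing_error_range <= 0))
    stop("mixing_error_range must be a positive interval")
  if (!all(peak_time_set %in% c(30, 120, 300, 600)))
    stop("peak_time_set must be a subset of {30, 120, 300, 600}")
  cfg <- as.list(environment())
  cfg$class_proportions <- setNames(as.numeric(class_proportions),
                                    c("Unaffected", "Gradual", "Digital"))
  structure(cfg, class = "phospho_sim_config")
}

# deterministic largest-remainder apportionment of n into proportions p
apportion <- function(n, p) {
  base <- floor(n * p)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * p - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

# batch layout: channel 1 unstim, 2-5 N4, 6-9 weak ligand (T4 in batches
# 1-3, G4 in 4-6); spare channel 10 unused and not exported.
phospho_batch_layout <- function(n_technical = 1L) {
  times <- c(30, 120, 300, 600)
  rows <- list()
  for (b in 1:6) {
    weak <- if (b <= 3) "T4" else "G4"
    wrep <- if (b <= 3) b else b - 3L
    rows[[b]] <- data.frame(
      batch = b,
      channel = 1:9,
      ligand = c("unstim", rep("N4", 4), rep(weak, 4)),
      time = c(0, times, times),
      biorep = c(b, rep(b, 4), rep(wrep, 4)),
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, rows)
  ann <- ann[rep(seq_len(nrow(ann)), each = n_technical), ]
  ann$techrep <- rep(seq_len(n_technical), times = 54)
  ann$sample_id <- paste(ann$batch, ann$channel, ann$ligand, ann$time,
                         ann$biorep, ann$techrep, sep = ".")
  rownames(ann) <- NULL
  ann
}

# true per-ligand amplitudes and per-site kinetic parameters
phospho_truth <- function(cfg) {
  counts <- apportion(cfg$n_sites, cfg$class_proportions)
  classes <- c(rep(c("Unaffected", "Gradual", "Digital"), counts),
               rep("Null", cfg$n_unresponsive))
  n <- length(classes)
  amp <- runif(n, cfg$amplitude_range[1], cfg$amplitude_range[2])
  dirn <- sample(c(1, -1), n, replace = TRUE,
                 prob = c(1 - cfg$down_fraction, cfg$down_fraction))
  tp <- sample(rep(cfg$peak_time_set, length.out = max(n, length(cfg$peak_time_set))))[seq_len(n)]
  loss_t4 <- loss_g4 <- numeric(n)
  gi <- classes == "Gradual"
  s <- runif(sum(gi), cfg$gradual_score_range[1], cfg$gradual_score_range[2])
  loss_t4[gi] <- clip(s - cfg$gradual_spread, 0, 100)
  loss_g4[gi] <- clip(s + cfg$gradual_spread, 0, 100)
  loss_t4[classes == "Digital"] <- 100
  loss_g4[classes == "Digital"] <- 100
  amp[classes == "Null"] <- 0
  data.frame(
    site_id = sprintf("site%04d", seq_len(n)),
    true_class = classes,
    direction = dirn,
    amp_n4 = amp,
    amp_t4 = amp * (1 - loss_t4 / 100),
    amp_g4 = amp * (1 - loss_g4 / 100),
    peak_time = tp,
    loss_t4 = loss_t4,
    loss_g4 = loss_g4,
    true_score = ifelse(classes == "Null", NA_real_, (loss_t4 + loss_g4) / 2),
    stringsAsFactors = FALSE)
}

#' Simulate a multiplexed phosphoproteomics time course
#'
#' Generates raw (linear-scale) site x sample intensities with the
#' structure the downstream analysis assumes: per-site gamma-pulse
#' kinetics whose per-ligand amplitudes encode the ground-truth response
#' class, per-(site, batch) offsets, per-channel mixing biases (with
#' matched channel totals so that [correct_mixing()] can undo them),
#' measurement noise, random and intensity-dependent missingness, and
#' Beta-distributed localization scores.
#'
#' @param config a [phospho_sim_config()].
#' @return a list of class `phospho_sim` with elements `intensity` (linear
#'   scale, `NA` = missing), `samples`, `sites`, `channel_totals`
#'   (batch x channel matrix of summed non-modified signal), `truth`
#'   (hidden ground truth, one record per site) and `config`.
#' @export
simulate_phospho_dataset <- function(config) {
  stopifnot(inherits(config, "phospho_sim_config"))
  withr::with_seed(config$seed, {
    truth <- phospho_truth(config)
    ann <- phospho_batch_layout(config$n_technical)
    n <- nrow(truth)
    m <- nrow(ann)

    baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
    batch_off <- matrix(rnorm(n * 6, 0, config$batch_sd), n, 6)

    amp <- cbind(unstim = 0, N4 = truth$amp_n4, T4 = truth$amp_t4,
                 G4 = truth$amp_g4)
    lig_idx <- match(ann$ligand, colnames(amp))
    log2_true <- matrix(0, n, m)
    for (j in seq_len(m)) {
      kin <- amp[, lig_idx[j]] * truth$direction *
        pulse_response(ann$time[j], truth$peak_time)
      log2_true[, j] <- baseline + kin + batch_off[, ann$batch[j]]
    }
    noise <- matrix(rnorm(n * m, 0, config$noise_sd), n, m)
    log2_val <- log2_true + noise

    mix <- matrix(runif(6 * 9, config$mixing_error_range[1],
                        config$mixing_error_range[2]), 6, 9,
                  dimnames = list(paste0("batch", 1:6), paste0("ch", 1:9)))
    lin <- 2^log2_val * rep(mix[cbind(ann$batch, ann$channel)], each = n)

    p_lod <- plogis((config$missing_lod - log2_val) / config$missing_scale)
    miss <- matrix(runif(n * m), n, m) < config$missing_rate_random |
      matrix(runif(n * m), n, m) < p_lod
    lin[miss] <- NA_real_

    residue <- sample(c("S", "T", "Y"), n, replace = TRUE,
                      prob = c(0.765, 0.165, 0.07))
    loc <- matrix(100 * rbeta(n * config$n_loc_replicates,
                              config$localization_alpha,
                              config$localization_beta),
                  n, config$n_loc_replicates,
                  dimnames = list(NULL, paste0("loc_score_rep",
                                               seq_len(config$n_loc_replicates))))
    sites <- data.frame(
      site_id = truth$site_id,
      protein_id = sprintf("PROT%04d", sample(seq_len(max(2, n %/% 3)), n,
                                              replace = TRUE)),
      residue = residue,
      position = sample(1:1200, n, replace = TRUE),
      fraction = ifelse(residue == "Y", "pY-IP", "TiO2"),
      stringsAsFactors = FALSE)
    sites <- cbind(sites, as.data.frame(loc))

    dimnames(lin) <- list(truth$site_id, ann$sample_id)
    totals <- 1e9 * mix
    structure(list(intensity = lin, samples = ann, sites = sites,
                   channel_totals = totals, truth = truth, config = config),
              class = "phospho_sim")
  })
}

#' True log2 fold-change kinetics of simulated sites
#'
#' Evaluates the noiseless kinetic curve of each generated site for one
#' ligand at the given times, on the same scale as
#' [fold_change_kinetics()] output.
#'
#' @param truth the `truth` element of a [simulate_phospho_dataset()] result.
#' @param ligand one of `"N4"`, `"T4"`, `"G4"`.
#' @param times time points in seconds.
#' @return matrix, sites x times, of true log2 fold changes.
#' @export
true_fold_change <- function(truth, ligand, times = c(0, 30, 120, 300, 600)) {
  amp <- switch(ligand, N4 = truth$amp_n4, T4 = truth$amp_t4,
                G4 = truth$amp_g4,
                stop("unknown ligand: ", ligand))
  out <- outer(seq_len(nrow(truth)), times, function(i, t)
    amp[i] * truth$direction[i] * pulse_response(t, truth$peak_time[i]))
  dimnames(out) <- list(truth$site_id, times)
  out
}
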