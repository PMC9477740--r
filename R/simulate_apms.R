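#' Protein-group table container for AP-MS data
#'
#' @param intensity numeric matrix, preys x samples, linear-scale
#'   intensities (`NA` = missing).
#' @param samples data.frame with one row per column: `bait`, `genotype`
#'   (`OST` or `WT`), `ligand`, `time`, `biorep`, `techrep`.
#' @param preys data.frame with one row per row of `intensity`:
#'   `prey_id`, `score` (identification score), `contaminant` (logical),
#'   `molar_mass` (g/mol), `n_peptides` (theoretical tryptic peptides,
#'   the iBAQ divisor).
#' @return an object of class `protein_groups`.
#' @export
protein_groups <- function(intensity, samples, preys) {
  stopifnot(is.matrix(intensity),
            nrow(samples) == ncol(intensity),
            nrow(preys) == nrow(intensity))
  needed <- c("bait", "genotype", "ligand", "time", "biorep", "techrep")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols))
    stop("sample annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(c("prey_id", "score", "contaminant", "molar_mass", "n_peptides")
           %in% names(preys)))
    stop("prey annotation incomplete")
  if (any(preys$n_peptides < 1)) stop("n_peptides must be >= 1")
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  rownames(intensity) <- preys$prey_id
  structure(list(intensity = intensity, samples = samples, preys = preys),
            class = "protein_groups")
}

#' @export
print.protein_groups <- function(x, ...) {
  cat(sprintf("protein_groups: %d preys x %d samples (%d OST, %d WT)\n",
              nrow(x$intensity), ncol(x$intensity),
              sum(x$samples$genotype == "OST"),
              sum(x$samples$genotype == "WT")))
  invisible(x)
}

#' Configuration of the AP-MS simulator
#'
#' Emulates the tagged-bait versus wild-type design: OST samples carry
#' background binding plus the bait and, for true interactors, signal
#' proportional to the interaction stoichiometry and bait abundance; WT
#' samples carry background only. Conditions are unstimulated plus
#' N4/T4/G4 at 30, 120 and 300 s, with six biological replicates for
#' unstimulated and N4 and three for T4 and G4, mirrored in WT.
#'
#' @param bait bait id (e.g. `"Cd3z"`).
#' @param n_preys number of non-bait preys.
#' @param n_true_interactors number of preys with nonzero true
#'   stoichiometry (must be `<= n_preys`).
#' @param background_mu,background_sigma per-prey background-binding mean
#'   log2 intensity is drawn from `N(background_mu, background_sigma)`.
#' @param noise_sd per-measurement log2 noise s.d.
#' @param bait_intensity linear MS intensity of the bait in OST samples.
#' @param bait_n_peptides theoretical peptide count of the bait.
#' @param base_stoich_range unstimulated (basal) stoichiometry interval of
#'   true interactors.
#' @param peak_stoich_range peak N4 stoichiometry interval.
#' @param peak_time_set candidate stoichiometry peak times (seconds).
#' @param missing_lod,missing_scale soft limit of detection (log2) and
#'   logistic scale of intensity-dependent dropout.
#' @param contaminant_fraction fraction of preys flagged as contaminants.
#' @param true_stoich_kinetics optional precomputed truth table (as
#'   returned in `truth`) overriding the random interactor draw.
#' @param seed integer seed.
#' @return an object of class `apms_sim_config`.
#' @export
apms_sim_config <- function(bait = "Cd3z",
                            n_preys = 200,
                            n_true_interactors = 10,
                            background_mu = 24,
                            background_sigma = 1.2,
                            noise_sd = 0.3,
                            bait_intensity = 4e9,
                            bait_n_peptides = 20,
                            base_stoich_range = c(0.01, 0.04),
                            peak_stoich_range = c(0.2, 0.6),
                            peak_time_set = c(30, 120, 300),
                            missing_lod = 22,
                            missing_scale = 1,
                            contaminant_fraction = 0.05,
                            true_stoich_kinetics = NULL,
                            seed = 1L) {
  if (length(bait) != 1 || !nzchar(bait)) stop("a single non-empty bait id is required")
  if (n_preys < 1) stop("n_preys must be >= 1")
  if (n_true_interactors > n_preys)
    stop("n_true_interactors must be <= n_preys")
  if (n_true_interactors < 0) stop("n_true_interactors must be >= 0")
  structure(as.list(environment()), class = "apms_sim_config")
}

apms_layout <- function(bait) {
  times <- c(30, 120, 300)
  one <- function(genotype) {
    rows <- list(data.frame(genotype = genotype, ligand = "unstim", time = 0,
                            biorep = 1:6))
    for (lig in c("N4", "T4", "G4")) {
      nrep <- if (lig == "N4") 6 else 3
      for (t in times)
        rows[[length(rows) + 1]] <-
          data.frame(genotype = genotype, ligand = lig, time = t,
                     biorep = seq_len(nrep))
    }
    do.call(rbind, rows)
  }
  ann <- rbind(one("OST"), one("WT"))
  ann$bait <- bait
  ann$techrep <- 1L
  ann$sample_id <- paste(ann$bait, ann$genotype, ann$ligand, ann$time,
                         ann$biorep, ann$techrep, sep = ".")
  rownames(ann) <- NULL
  ann
}

# per-interactor stoichiometry truth: log2FC archetype scaled per ligand
apms_truth <- function(cfg) {
  n <- cfg$n_preys
  prey_id <- sprintf("prey%03d", seq_len(n))
  is_int <- c(rep(TRUE, cfg$n_true_interactors),
              rep(FALSE, n - cfg$n_true_interactors))
  base <- ifelse(is_int, runif(n, cfg$base_stoich_range[1],
                               cfg$base_stoich_range[2]), 0)
  peak <- ifelse(is_int, runif(n, cfg$peak_stoich_range[1],
                               cfg$peak_stoich_range[2]), 0)
  tp <- sample(cfg$peak_time_set, n, replace = TRUE)
  loss_t4 <- runif(n, 0, 100)
  loss_g4 <- runif(n, 0, 100)
  data.frame(prey_id = prey_id, is_true_interactor = is_int,
             base_stoich = base, peak_stoich = peak, peak_time = tp,
             loss_t4 = ifelse(is_int, loss_t4, NA_real_),
             loss_g4 = ifelse(is_int, loss_g4, NA_real_),
             true_score = ifelse(is_int, (loss_t4 + loss_g4) / 2, NA_real_),
             stringsAsFactors = FALSE)
}

# true stoichiometry of prey i at (ligand, time); log2FC relative to the
# basal stoichiometry follows amp_lig * pulse(t), with amplitude scaled by
# the per-ligand loss so that AUC losses match the stored truth.
true_stoichiometry <- function(truth, ligand, time) {
  amp_n4 <- log2(pmax(truth$peak_stoich, 1e-12) / pmax(truth$base_stoich, 1e-12))
  fac <- switch(ligand,
                unstim = 0,
                N4 = 1,
                T4 = 1 - truth$loss_t4 / 100,
                G4 = 1 - truth$loss_g4 / 100)
  lfc <- amp_n4 * fac * pulse_response(time, truth$peak_time)
  out <- truth$base_stoich * 2^lfc
  out[!truth$is_true_interactor] <- 0
  out
}

#' Simulate an OST versus wild-type AP-MS experiment
#'
#' @param config an [apms_sim_config()].
#' @return a list of class `apms_sim` with elements `pg` (a
#'   [protein_groups()] table including the bait row), `truth` and
#'   `config`.
#' @export
simulate_apms_dataset <- function(config) {
  stopifnot(inherits(config, "apms_sim_config"))
  withr::with_seed(config$seed, {
    truth <- if (is.null(config$true_stoich_kinetics)) apms_truth(config)
             else config$true_stoich_kinetics
    ann <- apms_layout(config$bait)
    n <- nrow(truth)
    m <- nrow(ann)

    n_pep <- sample(5:40, n, replace = TRUE)
    bg_mu <- rnorm(n, config$background_mu, config$background_sigma)
    bait_abund <- config$bait_intensity / config$bait_n_peptides

    lin <- matrix(0, n, m)
    for (j in seq_len(m)) {
      bg <- 2^(bg_mu + rnorm(n, 0, config$noise_sd))
      sig <- 0
      if (ann$genotype[j] == "OST") {
        st <- true_stoichiometry(truth, ann$ligand[j], ann$time[j])
        sig <- st * bait_abund * n_pep * 2^rnorm(n, 0, config$noise_sd)
      }
      lin[, j] <- bg + sig
    }
    # bait row: strong constant signal in OST, background-level in WT
    bait_row <- ifelse(ann$genotype == "OST",
                       config$bait_intensity * 2^rnorm(m, 0, config$noise_sd),
                       2^(config$background_mu + rnorm(m, 0, config$noise_sd)))
    lin <- rbind(lin, bait_row)

    lg <- log2(lin)
    p_lod <- plogis((config$missing_lod - lg) / config$missing_scale)
    lin[matrix(runif(length(lin)), nrow(lin)) < p_lod] <- NA_real_

    preys <- data.frame(
      prey_id = c(truth$prey_id, config$bait),
      score = c(runif(n, -20, 300), 500),
      contaminant = c(runif(n) < config$contaminant_fraction, FALSE),
      molar_mass = c(runif(n, 2e4, 2e5), 7e4),
      n_peptides = c(n_pep, config$bait_n_peptides),
      stringsAsFactors = FALSE)
    preys$contaminant[truth$is_true_interactor] <- FALSE
    preys$score[preys$prey_id %in% truth$prey_id[truth$is_true_interactor]] <-
      abs(preys$score[preys$prey_id %in% truth$prey_id[truth$is_true_interactor]])

    pg <- protein_groups(lin, ann, preys)
    structure(list(pg = pg, truth = truth, config = config),
              class = "apms_sim")
  })
}

#' Simulate a kinase-substrate map
#'
#' Samples a distinct substrate set per kinase from a pool of site ids,
#' optionally concentrating one designated kinase's substrates in a given
#' subset (e.g. the Digital sites) for enrichment-recovery tests.
#'
#' @param n_kinases number of kinases.
#' @param substrates_per_kinase substrates sampled per kinase (must be
#'   `<= length(site_pool)`).
#' @param site_pool character vector of candidate substrate site ids.
#' @param seed integer seed.
#' @param biased_kinase optional kinase name whose substrates are drawn
#'   from `biased_pool` only.
#' @param biased_pool site ids the biased kinase draws from.
#' @return named list, kinase id to character vector of substrate ids.
#' @export
simulate_kinase_map <- function(n_kinases, substrates_per_kinase, site_pool,
                                seed = 1L, biased_kinase = NULL,
                                biased_pool = NULL) {
  if (substrates_per_kinase > length(site_pool))
    stop("substrates_per_kinase exceeds the site pool")
  if (n_kinases == 0) return(setNames(list(), character(0)))
  withr::with_seed(seed, {
    kin <- sprintf("KIN%02d", seq_len(n_kinases))
    map <- lapply(kin, function(k)
      sort(sample(site_pool, substrates_per_kinase)))
    names(map) <- kin
    if (!is.null(biased_kinase)) {
      if (is.null(biased_pool)) stop("biased_pool required with biased_kinase")
      map[[biased_kinase]] <-
        sort(sample(biased_pool, min(substrates_per_kinase, length(biased_pool))))
    }
    map
  })
}

#' Simulate a whole-proteome table with known copy numbers
#'
#' Draws true per-cell protein copy numbers and molar masses, flags
#' `n_histones` proteins as histones, and rescales the histone copies so
#' that the total histone mass per cell equals the DNA mass of a diploid
#' mouse cell -- the anchoring assumption of the proteomic ruler, which
#' makes zero-noise recovery exact. Per-replicate MS signal is
#' proportional to copies x molar mass with a replicate-specific scale.
#'
#' @param n_proteins number of non-histone proteins.
#' @param n_histones number of histone proteins.
#' @param n_replicates biological replicates.
#' @param noise_sd log2-scale multiplicative signal noise.
#' @param seed integer seed.
#' @return list of class `proteome_sim` with `records` (a data.frame with
#'   `protein_id`, `molar_mass`, `is_histone` and `signal_rep<k>` columns)
#'   and `truth` (`protein_id`, `true_copies`).
#' @export
simulate_proteome <- function(n_proteins = 500, n_histones = 10,
                              n_replicates = 3, noise_sd = 0, seed = 1L) {
  if (n_histones < 1) stop("at least one histone is required")
  withr::with_seed(seed, {
    n <- n_proteins + n_histones
    id <- c(sprintf("PR%04d", seq_len(n_proteins)),
            sprintf("HIST%02d", seq_len(n_histones)))
    mass <- c(10^runif(n_proteins, 4.2, 5.5), runif(n_histones, 11e3, 23e3))
    copies <- c(10^runif(n_proteins, 3, 6.5), 10^runif(n_histones, 5.5, 6.5))
    hist <- c(rep(FALSE, n_proteins), rep(TRUE, n_histones))
    # anchor: total histone mass (g) per cell = mDNA
    hist_mass <- sum(copies[hist] * mass[hist]) / .tcr_avogadro
    copies[hist] <- copies[hist] * (.tcr_mdna_g / hist_mass)
    sig <- sapply(seq_len(n_replicates), function(r) {
      scale_r <- 10^runif(1, -3, -2)
      scale_r * copies * mass * 2^rnorm(n, 0, noise_sd)
    })
    colnames(sig) <- paste0("signal_rep", seq_len(n_replicates))
    records <- data.frame(protein_id = id, molar_mass = mass,
                          is_histone = hist, stringsAsFactors = FALSE)
    records <- cbind(records, as.data.frame(sig))
    structure(list(records = records,
                   truth = data.frame(protein_id = id, true_copies = copies,
                                      stringsAsFactors = FALSE)),
              class = "proteome_sim")
  })
}
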