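#' Pipeline configuration
#'
#' Collects every analysis threshold (defaults are the study's values)
#' together with the simulator configurations and seeds. Round-trips
#' losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param localization_threshold localization-score cutoff (percent).
#' @param p_threshold ANOVA and Tukey significance threshold.
#' @param fc_threshold linear fold-change threshold of the regulation call.
#' @param class_bounds discrimination-score class boundaries.
#' @param enrichment_p,enrichment_fold,enrichment_k significance criteria
#'   of [kinase_enrichment()].
#' @param bin_width enrichment score-bin width (percent).
#' @param interactor_fc_min,interactor_fdr_max interactor-call thresholds.
#' @param n_imputation_repeats impute/test repeats of [test_interactions()].
#' @param imputation_seed seed of the imputation draws (phospho and AP-MS).
#' @param bait_copies bait copies per cell used for complex-abundance
#'   reporting when no measured bait copy number is supplied.
#' @param n_kinases,substrates_per_kinase simulated kinase-substrate map.
#' @param phospho_sim a [phospho_sim_config()].
#' @param apms_sim an [apms_sim_config()].
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(localization_threshold = 75,
                            p_threshold = 0.05,
                            fc_threshold = 1.5,
                            class_bounds = c(40, 80),
                            enrichment_p = 0.05,
                            enrichment_fold = 2,
                            enrichment_k = 2,
                            bin_width = 10,
                            interactor_fc_min = 10,
                            interactor_fdr_max = 0.05,
                            n_imputation_repeats = 10,
                            imputation_seed = 1L,
                            bait_copies = 1e5,
                            n_kinases = 12,
                            substrates_per_kinase = 15,
                            phospho_sim = phospho_sim_config(),
                            apms_sim = apms_sim_config()) {
  stopifnot(localization_threshold >= 0, localization_threshold <= 100,
            p_threshold > 0, p_threshold <= 1, fc_threshold >= 1,
            length(class_bounds) == 2, bin_width > 0,
            interactor_fc_min >= 1, interactor_fdr_max > 0,
            n_imputation_repeats >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the phosphoproteomics pipeline end to end
#'
#' Simulation (or an imported table), preprocessing, replicate
#' correlation, per-ligand regulation analysis, overlap summary,
#' discrimination scoring and classification, kinetic-group partition and
#' kinase-substrate enrichment. When `outdir` is given, every stage table
#' is written as annotated TSV carrying the configuration hash; reruns
#' with an identical configuration are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory (created if needed).
#' @param sim optional pre-built input (a `phospho_sim` or the list
#'   returned by [read_phospho_tsv()]); by default the generator runs
#'   with `config$phospho_sim`.
#' @param kinase_map optional named list kinase -> substrate site ids; by
#'   default a map is simulated over the scored sites.
#' @return list of class `phospho_pipeline` with elements `pset`,
#'   `correlation`, `regulation`, `regulated_sets`, `overlaps`, `scores`,
#'   `groups`, `enrichment`, `summary`.
#' @export
run_phospho_pipeline <- function(config = pipeline_config(), outdir = NULL,
                                 sim = NULL, kinase_map = NULL) {
  if (is.null(sim)) sim <- simulate_phospho_dataset(config$phospho_sim)
  if (!nrow(sim$intensity)) stop("no sites in the input table")
  pset <- preprocess_phospho(sim, config$localization_threshold,
                             config$imputation_seed)
  corr <- sample_correlation(pset)
  reg <- test_regulation(pset, fc_threshold = config$fc_threshold,
                         p_threshold = config$p_threshold)
  reg_sets <- lapply(split(reg, reg$ligand),
                     function(d) d$site_id[d$regulated])
  overlaps <- overlap_summary(reg_sets)

  regulated_any <- unique(reg$site_id[reg$regulated])
  scored_ids <- sort(intersect(regulated_any, quantified_complete(pset)))
  scores <- groups <- enrichment <- NULL
  if (length(scored_ids)) {
    scores <- score_sites(pset, scored_ids, bounds = config$class_bounds)
    sub <- subset_sites(pset, pset$sites$site_id %in% scored_ids)
    n4 <- fold_change_kinetics(sub, "N4")
    groups <- partition_groups(n4, scores$class[match(rownames(n4),
                                                      scores$site_id)])
    scores$group_id <- groups$group_id[match(scores$site_id, groups$site_id)]
    if (is.null(kinase_map))
      kinase_map <- simulate_kinase_map(config$n_kinases,
                                        min(config$substrates_per_kinase,
                                            length(scored_ids)),
                                        scored_ids,
                                        seed = config$phospho_sim$seed)
    score_vec <- setNames(scores$score, scores$site_id)
    enrichment <- kinase_enrichment(kinase_map, score_vec,
                                    bin_width = config$bin_width,
                                    p_threshold = config$enrichment_p,
                                    fold_min = config$enrichment_fold,
                                    k_min = config$enrichment_k)
  }

  summary_df <- rbind(
    data.frame(metric = paste0("sites_", c("S", "T", "Y")),
               value = as.integer(table(factor(pset$sites$residue,
                                               levels = c("S", "T", "Y"))))),
    data.frame(metric = paste0("regulated_", names(reg_sets)),
               value = lengths(reg_sets)),
    data.frame(metric = paste0("class_",
                               c("Unaffected", "Gradual", "Digital")),
               value = if (is.null(scores)) c(0L, 0L, 0L)
                       else as.integer(table(factor(scores$class,
                                                    levels = c("Unaffected",
                                                               "Gradual",
                                                               "Digital"))))))
  rownames(summary_df) <- NULL

  res <- structure(list(pset = pset, correlation = corr, regulation = reg,
                        regulated_sets = reg_sets, overlaps = overlaps,
                        scores = scores, groups = groups,
                        enrichment = enrichment, summary = summary_df),
                   class = "phospho_pipeline")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    meta <- list(config_hash = rlang::hash(config),
                 simulation_seed = config$phospho_sim$seed,
                 imputation_seed = config$imputation_seed)
    write_result_tsv(reg, file.path(outdir, "regulation.tsv"), meta)
    corr_df <- data.frame(sample_id = rownames(corr),
                          as.data.frame(corr, check.names = FALSE))
    write_result_tsv(corr_df, file.path(outdir, "correlation.tsv"), meta)
    if (!is.null(scores))
      write_result_tsv(scores, file.path(outdir, "sites_scored.tsv"), meta)
    if (!is.null(enrichment))
      write_result_tsv(enrichment, file.path(outdir, "enrichment.tsv"), meta)
    write_result_tsv(summary_df, file.path(outdir, "summary.tsv"), meta)
  }
  res
}

#' Run the interactome pipeline end to end
#'
#' Simulation (or an imported protein-group table), cleaning, median
#' normalization, technical-replicate averaging, repeated-imputation
#' Welch testing, volcano-asymmetry FDR, interactor calls, interaction
#' stoichiometry with per-interaction discrimination scores, and
#' complex-abundance reporting together with a proteomic-ruler copy-number
#' table from a simulated whole proteome.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @param sim optional pre-built `apms_sim`.
#' @param proteome optional `proteome_sim` (default: simulated with the
#'   AP-MS seed).
#' @return list of class `interactome_pipeline` with elements `pg`,
#'   `tests`, `interactors`, `stoichiometry`, `stoich_scores`,
#'   `copy_numbers`, `complexes`.
#' @export
run_interactome_pipeline <- function(config = pipeline_config(),
                                     outdir = NULL, sim = NULL,
                                     proteome = NULL) {
  if (is.null(sim)) sim <- simulate_apms_dataset(config$apms_sim)
  bait <- unique(sim$pg$samples$bait)[1]
  if (!bait %in% sim$pg$preys$prey_id) stop("bait row missing from the table")
  pg <- clean_protein_groups(sim$pg)
  pg <- median_normalize(pg)
  pg <- average_technical_geomean(pg)
  tests <- test_interactions(pg, n_repeats = config$n_imputation_repeats,
                             seed = config$imputation_seed,
                             exclude_preys = bait)
  tests <- asymmetry_fdr(tests)
  tests <- call_interactors(tests, fc_min = config$interactor_fc_min,
                            fdr_max = config$interactor_fdr_max)
  interactors <- sort(unique(tests$prey_id[tests$interactor]))

  stoich <- stoich_scores <- complexes <- NULL
  if (length(interactors)) {
    stoich <- interaction_stoichiometry(pg, bait, interactors)
    stoich_scores <- do.call(rbind, lapply(interactors, function(pid) {
      d <- stoich[stoich$prey_id == pid, ]
      out <- tryCatch(stoichiometry_discrimination(d),
                      error = function(e)
                        data.frame(auc_g4 = NA_real_, auc_t4 = NA_real_,
                                   auc_n4 = NA_real_, loss_g4 = NA_real_,
                                   loss_t4 = NA_real_, score = NA_real_,
                                   class = NA_character_))
      cbind(prey_id = pid, out)
    }))
    peak <- tapply(stoich$stoichiometry, stoich$prey_id, max, na.rm = TRUE)
    complexes <- data.frame(
      prey_id = names(peak),
      peak_stoichiometry = as.numeric(peak),
      complexes_per_cell = complex_abundance(pmax(as.numeric(peak), 0),
                                             config$bait_copies),
      stringsAsFactors = FALSE)
  }
  if (is.null(proteome))
    proteome <- simulate_proteome(seed = config$apms_sim$seed)
  copy_numbers <- ruler_table(proteome$records)

  res <- structure(list(pg = pg, tests = tests, interactors = interactors,
                        stoichiometry = stoich,
                        stoich_scores = stoich_scores,
                        copy_numbers = copy_numbers, complexes = complexes),
                   class = "interactome_pipeline")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    meta <- list(config_hash = rlang::hash(config),
                 simulation_seed = config$apms_sim$seed,
                 imputation_seed = config$imputation_seed)
    write_result_tsv(tests, file.path(outdir, "interaction_tests.tsv"), meta)
    if (!is.null(stoich))
      write_result_tsv(stoich, file.path(outdir, "stoichiometry.tsv"), meta)
    if (!is.null(stoich_scores))
      write_result_tsv(stoich_scores, file.path(outdir, "stoichiometry_scores.tsv"),
                       meta)
    write_result_tsv(copy_numbers, file.path(outdir, "copy_numbers.tsv"), meta)
    if (!is.null(complexes))
      write_result_tsv(complexes, file.path(outdir, "complex_abundance.tsv"),
                       meta)
  }
  res
}
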