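# Shared fixtures built in code.

# Minimal phospho_set: one matrix plus hand-rolled annotation.
toy_pset <- function(values, ligand, time, biorep,
                     batch = 1L, channel = seq_along(ligand),
                     techrep = 1L, site_ids = NULL, observed = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  ann <- data.frame(batch = rep_len(batch, ncol(values)),
                    channel = rep_len(channel, ncol(values)),
                    ligand = ligand, time = time,
                    biorep = biorep,
                    techrep = rep_len(techrep, ncol(values)),
                    stringsAsFactors = FALSE)
  if (is.null(site_ids)) site_ids <- sprintf("s%03d", seq_len(n))
  sites <- data.frame(site_id = site_ids,
                      protein_id = paste0("P", seq_len(n)),
                      residue = "S", position = seq_len(n), fraction = "TiO2",
                      loc_score_rep1 = 99, stringsAsFactors = FALSE)
  if (is.null(observed)) observed <- !is.na(values)
  phospho_set(values, ann, sites, observed)
}

# Minimal protein_groups table: intensity matrix with OST/WT annotation.
toy_pg <- function(intensity, genotype, ligand, time, biorep,
                   prey_ids = NULL, n_peptides = 10, score = 100,
                   contaminant = FALSE, bait = "BAIT") {
  intensity <- as.matrix(intensity)
  n <- nrow(intensity)
  if (is.null(prey_ids)) prey_ids <- sprintf("prey%02d", seq_len(n))
  ann <- data.frame(bait = bait, genotype = genotype, ligand = ligand,
                    time = time, biorep = biorep, techrep = 1L,
                    stringsAsFactors = FALSE)
  ann$sample_id <- paste(ann$bait, ann$genotype, ann$ligand, ann$time,
                         ann$biorep, ann$techrep, sep = ".")
  preys <- data.frame(prey_id = prey_ids,
                      score = rep_len(score, n),
                      contaminant = rep_len(contaminant, n),
                      molar_mass = 5e4,
                      n_peptides = rep_len(n_peptides, n),
                      stringsAsFactors = FALSE)
  protein_groups(intensity, ann, preys)
}

# Independent textbook one-way ANOVA + studentized-range oracle.
oracle_anova_tukey <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  n_i <- tapply(y, g, length)
  m_i <- tapply(y, g, mean)
  N <- length(y)
  grand <- mean(y)
  ssb <- sum(n_i * (m_i - grand)^2)
  ssw <- sum((y - m_i[g])^2)
  df1 <- k - 1
  df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  mse <- ssw / df2
  pairs <- utils::combn(levels(g), 2)
  tuk <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt(mse / 2 * (1 / n_i[a] + 1 / n_i[b]))
    q <- abs(m_i[b] - m_i[a]) / se
    ptukey(q, k, df2, lower.tail = FALSE)
  })
  list(anova_p = p,
       pairwise = data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                             corrected_p = tuk, stringsAsFactors = FALSE))
}

# Exhaustive-enumeration hypergeometric upper tail P(X >= k).
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Cache for expensive shared runs (test files run in one process).
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Default-condition phospho run: generator defaults, full analysis chain.
default_phospho_run <- function() {
  cached_fixture("phospho_default", function() {
    cfg <- phospho_sim_config()
    sim <- simulate_phospho_dataset(cfg)
    pset <- preprocess_phospho(sim, imputation_seed = cfg$seed)
    reg <- suppressMessages(test_regulation(pset))
    reg_sets <- lapply(split(reg, reg$ligand),
                       function(d) d$site_id[d$regulated])
    scored_ids <- sort(intersect(unique(reg$site_id[reg$regulated]),
                                 quantified_complete(pset)))
    scores <- score_sites(pset, scored_ids)
    list(sim = sim, pset = pset, reg = reg, reg_sets = reg_sets,
         scores = scores)
  })
}
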