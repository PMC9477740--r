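# tcrdiscrim

Quantifying T cell receptor (TCR) ligand discrimination from time-resolved
proteomics.

T cells mount very different responses to peptide–MHC ligands of different
TCR affinity (for OVA-specific OT-I cells: the strong agonist N4 versus the
weaker variants T4 and G4). `tcrdiscrim` implements, as a tested and
reusable pipeline, the statistics with which that discrimination is
measured from two data types:

* **TMT time-course phosphoproteomics** — site-level preprocessing (channel
  mixing correction, localization filtering at ≥ 75%, TiO2 / pY-IP fraction
  partitioning, low-quantile Gaussian imputation of fully missing
  conditions, between-batch normalization on shared conditions), one-way
  ANOVA with Tukey HSD to call TCR-regulated phospho-sites
  (p ≤ 0.05 and a time-point pair with corrected p ≤ 0.05 and |FC| ≥ 1.5),
  and the **discrimination score**;
* **AP-MS interactomics** (tagged bait vs wild type) — repeated-imputation
  Welch testing against pooled wild-type intensities, a volcano-asymmetry
  FDR, interactor calls (FC ≥ 10, FDR ≤ 0.05), iBAQ-based interaction
  stoichiometries and their discrimination scores, plus proteomic-ruler
  absolute copy numbers and complex abundances.

The central statistic: per site (or interaction), log2 fold-change kinetics
relative to the unstimulated baseline are integrated over the stimulation
time course (trapezoid rule). For each weak ligand *w*,

    loss_w = 100 × (1 − AUC_w / AUC_N4)   (clipped to [0, 100])

and the **discrimination score** is the mean of the available losses:
0% = affinity-independent response, 100% = N4-only response. Scores define
the response taxonomy **Unaffected** (≤ 40), **Gradual** (40–80] and
**Digital** (> 80), and kinase–substrate enrichment is profiled along the
score axis with hypergeometric tests.

Because raw mass-spectrometry data are not required, the package ships
seeded generators (`simulate_phospho_dataset()`, `simulate_apms_dataset()`,
`simulate_proteome()`, `simulate_kinase_map()`) that emulate the
multiplexed study design — six 10-plex TMT batches, 6 replicates for
unstimulated/N4 and 3 for T4/G4 — with hidden ground truth used by the
recovery tests.

## Worked example

The score of the illustrative kinetics with per-ligand AUCs 5.2 (G4), 9.3
(T4) and 14.6 (N4):

```r
library(tcrdiscrim)
ds <- discrimination_score(auc_g4 = 5.2, auc_t4 = 9.3, auc_n4 = 14.6)
round(ds)
#>   loss_g4 loss_t4 score
#> 1      64      36    50
classify_response(ds$score)
#> [1] "Gradual"
```

G4 loses 64% and T4 36% of the N4 response; the average loss (score) of 50%
places this site in the Gradual band.

An end-to-end synthetic run:

```r
cfg <- pipeline_config(
  phospho_sim = phospho_sim_config(n_sites = 120, n_unresponsive = 20, seed = 7))
res <- run_phospho_pipeline(cfg)
res$summary
#>             metric value
#> 1          sites_S   106
#> 2          sites_T    21
#> 3          sites_Y    13
#> 4     regulated_G4    61
#> 5     regulated_N4   115
#> 6     regulated_T4    74
#> 7 class_Unaffected    35
#> 8    class_Gradual    33
#> 9    class_Digital    33
```

The summary shows the site counts by residue, the per-ligand regulated-set
sizes — note the nesting with affinity, G4 ⊂ T4 ⊂ N4 in tendency — and the
class counts among scored sites. `res$scores` holds per-site AUCs, losses,
score, class and kinetic group; `res$enrichment` the kinase × score-bin
table. The interactome side works the same way:

```r
ires <- run_interactome_pipeline(cfg)
length(ires$interactors)
#> [1] 9
head(ires$stoich_scores[c("prey_id", "loss_g4", "loss_t4", "score", "class")], 3)
#>   prey_id   loss_g4  loss_t4    score   class
#> 1 prey001  12.28414 69.35156 40.81785 Gradual
#> 2 prey002  40.95135 60.05055 50.50095 Gradual
#> 3 prey003 100.00000 50.90657 75.45329 Gradual
```

Passing `outdir =` to either pipeline writes every stage table as annotated
TSV (missing = empty field, `#` metadata lines carrying the configuration
hash); reruns with the same configuration are byte-identical. Readers and
writers for the TSV dialects (`read_phospho_tsv()`,
`read_protein_groups_tsv()`, `read_kinase_map_tsv()`) accept user-supplied
tables in the same formats, and the configuration round-trips through YAML
(`write_pipeline_config()` / `read_pipeline_config()`).

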