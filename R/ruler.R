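# Avogadro's constant (1/mol) and the DNA mass of a diploid mouse cell
# (grams); the anchors of the proteomic-ruler relationship.
.tcr_avogadro <- 6.02214076e23
.tcr_mdna_pg <- 5.5209
.tcr_mdna_g <- .tcr_mdna_pg * 1e-12

#' Proteomic-ruler copy number
#'
#' Evaluates the proteomic-ruler relationship
#' `copies per cell = signal * N_A * mDNA / (M * histone_signal)`,
#' with `mDNA = 5.5209 pg` (diploid mouse cell) and `N_A` Avogadro's
#' constant. The histone MS signal anchors the total protein signal to
#' the cell's DNA mass.
#'
#' @param signal protein MS signal (vectorized).
#' @param molar_mass protein molar mass in g/mol (> 0).
#' @param histone_signal summed histone MS signal (> 0).
#' @return protein copies per cell.
#' @export
copy_number <- function(signal, molar_mass, histone_signal) {
  if (any(!(histone_signal > 0))) stop("histone_signal must be > 0")
  if (any(!(molar_mass > 0))) stop("molar_mass must be > 0")
  signal * .tcr_avogadro * .tcr_mdna_g / (molar_mass * histone_signal)
}

#' Copy-number table from a whole-proteome record set
#'
#' Per replicate, the histone MS signal is the sum over histone-flagged
#' records; per-replicate copy numbers follow [copy_number()] and are
#' averaged across replicates by the geometric mean over replicates with
#' a positive estimate (zero-signal replicates are excluded and logged).
#'
#' @param records data.frame with `protein_id`, `molar_mass`,
#'   `is_histone` and one or more `signal_rep<k>` columns.
#' @return data.frame: `protein_id`, `copies_per_cell`.
#' @export
ruler_table <- function(records) {
  sig_cols <- grep("^signal_rep", names(records), value = TRUE)
  if (!length(sig_cols)) stop("no signal_rep<k> columns found")
  if (!any(records$is_histone)) stop("no histone-flagged records")
  copies <- matrix(NA_real_, nrow(records), length(sig_cols))
  for (j in seq_along(sig_cols)) {
    s <- records[[sig_cols[j]]]
    hist_sig <- sum(s[records$is_histone], na.rm = TRUE)
    copies[, j] <- copy_number(s, records$molar_mass, hist_sig)
  }
  n_zero <- sum(copies <= 0 | is.na(copies))
  if (n_zero > 0)
    message(sprintf("ruler_table: %d non-positive replicate estimates excluded from the geometric mean", n_zero))
  est <- apply(copies, 1, function(x) {
    x <- x[!is.na(x) & x > 0]
    if (!length(x)) 0 else geomean(x)
  })
  data.frame(protein_id = records$protein_id, copies_per_cell = est,
             stringsAsFactors = FALSE)
}

#' Cellular abundance of a binary complex
#'
#' Complexes per cell = stoichiometry x bait copies, with the prey:bait
#' stoichiometry capped at 1 so a 1:1 complex count cannot exceed the
#' bait's copy number.
#'
#' @param stoichiometry prey:bait interaction stoichiometry (>= 0).
#' @param bait_copies bait copies per cell (>= 0).
#' @return complexes per cell (vectorized).
#' @export
complex_abundance <- function(stoichiometry, bait_copies) {
  stopifnot(all(stoichiometry >= 0, na.rm = TRUE),
            all(bait_copies >= 0, na.rm = TRUE))
  pmin(stoichiometry, 1) * bait_copies
}
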