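# All tables are TSV with '#'-prefixed header metadata lines; missing
# values are encoded as empty fields (never 0, never "NA") so zero and
# missing stay distinct.

#' Write a result table as annotated TSV
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param meta named list of metadata written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = ",")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an annotated TSV written by [write_result_tsv()]
#'
#' @param path file to read.
#' @return data.frame (metadata lines are skipped; empty fields read as
#'   `NA`).
#' @export
read_result_tsv <- function(path) {
  read.delim(path, comment.char = "#", sep = "\t", na.strings = "",
             check.names = FALSE, stringsAsFactors = FALSE)
}

# sample-id dialect <batch>.<channel>.<ligand>.<time>.<biorep>.<techrep>
parse_phospho_sample_ids <- function(ids) {
  parts <- strsplit(ids, ".", fixed = TRUE)
  if (any(lengths(parts) != 6))
    stop("sample columns must be named <batch>.<channel>.<ligand>.<time>.<biorep>.<techrep>")
  m <- do.call(rbind, parts)
  data.frame(batch = as.integer(m[, 1]), channel = as.integer(m[, 2]),
             ligand = m[, 3], time = as.numeric(m[, 4]),
             biorep = as.integer(m[, 5]), techrep = as.integer(m[, 6]),
             sample_id = ids, stringsAsFactors = FALSE)
}

#' Write a site-level phospho intensity table
#'
#' One row per site: `site_id, protein_id, residue, position, fraction`,
#' the localization-score columns, then one linear-intensity column per
#' sample named `<batch>.<channel>.<ligand>.<time>.<biorep>.<techrep>`.
#'
#' @param sim a `phospho_sim` (or any list with `intensity`, `samples`,
#'   `sites`).
#' @param path output file.
#' @param meta metadata lines, see [write_result_tsv()].
#' @return `path`, invisibly.
#' @export
write_phospho_tsv <- function(sim, path, meta = list()) {
  df <- cbind(sim$sites, as.data.frame(sim$intensity, check.names = FALSE))
  write_result_tsv(df, path, meta)
}

#' Read a site-level phospho intensity table
#'
#' @param path file in the [write_phospho_tsv()] dialect.
#' @return list with `intensity` (linear scale), `samples`, `sites`,
#'   suitable for [preprocess_phospho()] (no `channel_totals`: imported
#'   tables are assumed already mixing-corrected).
#' @export
read_phospho_tsv <- function(path) {
  df <- read_result_tsv(path)
  site_cols <- c("site_id", "protein_id", "residue", "position", "fraction",
                 grep("^loc_score_rep", names(df), value = TRUE))
  site_cols <- intersect(site_cols, names(df))
  sample_cols <- setdiff(names(df), site_cols)
  ann <- parse_phospho_sample_ids(sample_cols)
  intens <- as.matrix(df[sample_cols])
  rownames(intens) <- df$site_id
  list(intensity = intens, samples = ann,
       sites = df[site_cols])
}

#' Write a MaxQuant-style protein-group table
#'
#' Columns: `Gene name`, `Score`, `Contaminant` (`+` marker), `Molar
#' mass`, `Theoretical peptides`, then one column per sample named
#' `Intensity <bait>.<genotype>.<ligand>.<time>.<biorep>.<techrep>`.
#'
#' @param pg a [protein_groups()] table.
#' @param path output file.
#' @param meta metadata lines.
#' @return `path`, invisibly.
#' @export
write_protein_groups_tsv <- function(pg, path, meta = list()) {
  df <- data.frame(`Gene name` = pg$preys$prey_id,
                   Score = pg$preys$score,
                   Contaminant = ifelse(pg$preys$contaminant, "+", ""),
                   `Molar mass` = pg$preys$molar_mass,
                   `Theoretical peptides` = pg$preys$n_peptides,
                   check.names = FALSE, stringsAsFactors = FALSE)
  intens <- as.data.frame(pg$intensity, check.names = FALSE)
  names(intens) <- paste("Intensity", pg$samples$sample_id)
  write_result_tsv(cbind(df, intens), path, meta)
}

#' Read a MaxQuant-style protein-group table
#'
#' @param path file in the [write_protein_groups_tsv()] dialect.
#' @return a [protein_groups()] table.
#' @export
read_protein_groups_tsv <- function(path) {
  df <- read_result_tsv(path)
  int_cols <- grep("^Intensity ", names(df), value = TRUE)
  ids <- sub("^Intensity ", "", int_cols)
  parts <- strsplit(ids, ".", fixed = TRUE)
  if (any(lengths(parts) != 6))
    stop("intensity columns must be named 'Intensity <bait>.<genotype>.<ligand>.<time>.<biorep>.<techrep>'")
  m <- do.call(rbind, parts)
  ann <- data.frame(bait = m[, 1], genotype = m[, 2], ligand = m[, 3],
                    time = as.numeric(m[, 4]), biorep = as.integer(m[, 5]),
                    techrep = as.integer(m[, 6]), sample_id = ids,
                    stringsAsFactors = FALSE)
  contam <- df$Contaminant
  contam <- !is.na(contam) & contam == "+"
  preys <- data.frame(prey_id = df[["Gene name"]], score = df$Score,
                      contaminant = contam,
                      molar_mass = df[["Molar mass"]],
                      n_peptides = df[["Theoretical peptides"]],
                      stringsAsFactors = FALSE)
  intens <- as.matrix(df[int_cols])
  colnames(intens) <- ids
  protein_groups(intens, ann, preys)
}

#' Write a kinase-substrate map as two-column TSV
#'
#' @param map named list, kinase to substrate site ids.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kinase_map_tsv <- function(map, path) {
  df <- data.frame(kinase = rep(names(map), lengths(map)),
                   site_id = unlist(map, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write_result_tsv(df, path)
}

#' Read a kinase-substrate map from two-column TSV
#'
#' @param path file with columns `kinase` and `site_id`.
#' @return named list, kinase to substrate site ids.
#' @export
read_kinase_map_tsv <- function(path) {
  df <- read_result_tsv(path)
  lapply(split(df$site_id, df$kinase), unique)
}

#' Write / read the pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  yaml::write_yaml(strip(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  simplify <- function(x) {
    if (is.list(x) && length(x) && all(vapply(x, is.numeric, logical(1))) &&
        all(lengths(x) == 1)) {
      return(unlist(x))
    }
    x
  }
  args <- lapply(raw, simplify)
  args$phospho_sim <- do.call(phospho_sim_config, lapply(raw$phospho_sim, simplify))
  args$apms_sim <- do.call(apms_sim_config, lapply(raw$apms_sim, simplify))
  do.call(pipeline_config, args)
}
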