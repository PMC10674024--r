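MUTATION_COLUMNS <- c(
  "sample_id", "gene", "chrom", "pos", "ref", "alt", "variant_class",
  "protein_pos", "aa_ref", "aa_alt", "allele_fraction", "alteration_type"
)
MUTATION_REQUIRED <- c("sample_id", "gene", "variant_class")

SAMPLE_COLUMNS <- c(
  "sample_id", "ms_status_known", "tmb", "sensor_score", "mantis_score",
  "panel_id", "cna_fraction", "mmr_mutated", "mutation_count", "stage",
  "subtype_assigned"
)
SAMPLE_REQUIRED <- "sample_id"

VARIANT_CLASSES <- c(
  "missense", "nonsense", "synonymous", "frameshift",
  "inframe_indel", "splice", "other"
)

rename_columns <- function(tab, column_map) {
  if (length(column_map)) {
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (src %in% names(tab)) {
        names(tab)[names(tab) == src] <- canonical
      }
    }
  }
  tab
}

#' Load and validate a mutation/sample cohort
#'
#' Reads MAF-like mutation records and per-tumor sample records from TSV,
#' applies an optional column map (for heterogeneous source schemas), fills
#' missing optional columns with NA, and validates:
#' * required columns must be present (schema error naming the column);
#' * coordinates and allele fractions must parse (row-level error with line
#'   number);
#' * unknown variant classes are mapped to `"other"`;
#' * records labelled missense whose reference and alternate amino acids
#'   agree are rewritten to `"synonymous"` with a warning.
#'
#' @param mutations_path TSV of mutation records. Canonical columns:
#'   `sample_id, gene, chrom, pos, ref, alt, variant_class, protein_pos,
#'   aa_ref, aa_alt, allele_fraction, alteration_type`.
#' @param samples_path TSV of sample records. Canonical columns:
#'   `sample_id, ms_status_known, tmb, sensor_score, mantis_score, panel_id,
#'   cna_fraction, mmr_mutated, mutation_count, stage, subtype_assigned`.
#' @param column_map named list mapping canonical names to source column
#'   names, e.g. `list(sample_id = "Tumor_Sample_Barcode")`; may also be the
#'   `columns` entry of [read_config()].
#' @return list with data.frames `mutations` and `samples` in canonical
#'   layout; row counts equal the input files.
#' @export
load_cohort <- function(mutations_path, samples_path, column_map = list()) {
  mut <- read.delim(mutations_path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  smp <- read.delim(samples_path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  mut <- rename_columns(mut, column_map)
  smp <- rename_columns(smp, column_map)

  miss <- setdiff(MUTATION_REQUIRED, names(mut))
  if (length(miss)) {
    stop("mutation table missing required column(s): ", paste(miss, collapse = ", "))
  }
  miss <- setdiff(SAMPLE_REQUIRED, names(smp))
  if (length(miss)) {
    stop("sample table missing required column(s): ", paste(miss, collapse = ", "))
  }
  for (col in setdiff(MUTATION_COLUMNS, names(mut))) mut[[col]] <- NA
  for (col in setdiff(SAMPLE_COLUMNS, names(smp))) smp[[col]] <- NA
  mut <- mut[MUTATION_COLUMNS]
  smp <- smp[SAMPLE_COLUMNS]

  check_numeric <- function(x, name, rows_offset = 1L) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      stop("malformed ", name, " at line ", bad[1] + rows_offset,
        " of the mutation table: '", x[bad[1]], "'")
    }
    v
  }
  mut$pos <- check_numeric(mut$pos, "pos")
  mut$protein_pos <- check_numeric(mut$protein_pos, "protein_pos")
  mut$allele_fraction <- check_numeric(mut$allele_fraction, "allele_fraction")
  if (any(!is.na(mut$allele_fraction) &
          (mut$allele_fraction < 0 | mut$allele_fraction > 1))) {
    stop("allele_fraction outside [0, 1]")
  }

  unknown <- !is.na(mut$variant_class) & !(mut$variant_class %in% VARIANT_CLASSES)
  if (any(unknown)) mut$variant_class[unknown] <- "other"
  mut$variant_class[is.na(mut$variant_class)] <- "other"
  mut$alteration_type[is.na(mut$alteration_type)] <- "mutation"

  inconsistent <- mut$variant_class == "missense" &
    !is.na(mut$aa_ref) & !is.na(mut$aa_alt) & mut$aa_ref == mut$aa_alt
  if (any(inconsistent)) {
    warning(
      sum(inconsistent),
      " record(s) labelled missense with aa_ref == aa_alt rewritten to synonymous"
    )
    mut$variant_class[inconsistent] <- "synonymous"
  }

  if (any(!is.na(smp$tmb) & smp$tmb < 0)) stop("negative tmb in sample table")
  smp$mmr_mutated <- as.logical(smp$mmr_mutated)
  smp$ms_status_known[is.na(smp$ms_status_known)] <- "unknown"
  smp$stage[is.na(smp$stage)] <- "unknown"
  smp$subtype_assigned[is.na(smp$subtype_assigned)] <- "unknown"
  list(mutations = mut, samples = smp)
}

#' Write a cohort back to TSV
#'
#' Inverse of [load_cohort()]: `load_cohort(write_cohort(x))` round-trips all
#' valid records.
#'
#' @param cohort list with `mutations` and `samples` data.frames.
#' @param mutations_path,samples_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, mutations_path, samples_path) {
  write.table(cohort$mutations, mutations_path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  write.table(cohort$samples, samples_path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(c(mutations_path, samples_path))
}

#' Assign microsatellite subtype labels
#'
#' Deterministic composite labels from the evidence available per tumor:
#' * TMB > `tmb_htmb` (100): `MSS-htmb` (POLE-like hypermutated MSS) —
#'   overrides everything else;
#' * otherwise a known MS status wins when `known_status_wins` (default):
#'   known MSI-H is `MT-H`, known MSS is `MT-L`;
#' * otherwise TMB in \[`tmb_low`, `tmb_htmb`\] = \[16, 100\] is `MT-H`,
#'   TMB < 16 is `MT-L` (half-open at 16: `MT-L` is \[0, 16));
#' * otherwise MSIsensor >= 3.5 or MANTIS >= 0.4 is `MT-H`; scores present
#'   but below both cutoffs is `MT-L`;
#' * with no usable evidence the label is `unknown`.
#'
#' @param samples sample data.frame ([load_cohort()] layout) or a single row.
#' @param config thresholds from [somselect_config()].
#' @return character vector of labels (`MT-L`, `MT-H`, `MSS-htmb`,
#'   `unknown`), one per sample.
#' @export
#' @examples
#' s <- data.frame(
#'   sample_id = c("a", "b", "c"),
#'   ms_status_known = "unknown",
#'   tmb = c(10, 50, 150), sensor_score = NA, mantis_score = NA
#' )
#' classify_ms_status(s)
classify_ms_status <- function(samples, config = somselect_config()) {
  tmb <- if ("tmb" %in% names(samples)) samples$tmb else rep(NA_real_, nrow(samples))
  if (any(!is.na(tmb) & tmb < 0)) stop("negative tmb")
  known <- if ("ms_status_known" %in% names(samples)) {
    as.character(samples$ms_status_known)
  } else {
    rep("unknown", nrow(samples))
  }
  known[is.na(known)] <- "unknown"
  sensor <- if ("sensor_score" %in% names(samples)) samples$sensor_score else rep(NA_real_, nrow(samples))
  mantis <- if ("mantis_score" %in% names(samples)) samples$mantis_score else rep(NA_real_, nrow(samples))
  if (any(!is.na(sensor) & sensor < 0) || any(!is.na(mantis) & mantis < 0)) {
    stop("MSI scores must be non-negative")
  }

  n <- length(tmb)
  label <- rep("unknown", n)
  for (i in seq_len(n)) {
    if (!is.na(tmb[i]) && tmb[i] > config$tmb_htmb) {
      label[i] <- "MSS-htmb"
    } else if (config$known_status_wins && known[i] == "MSI-H") {
      label[i] <- "MT-H"
    } else if (config$known_status_wins && known[i] == "MSS") {
      label[i] <- "MT-L"
    } else if (!is.na(tmb[i])) {
      label[i] <- if (tmb[i] >= config$tmb_low) "MT-H" else "MT-L"
    } else if (known[i] == "MSI-H") {
      label[i] <- "MT-H"
    } else if (known[i] == "MSS") {
      label[i] <- "MT-L"
    } else if ((!is.na(sensor[i]) && sensor[i] >= config$sensor) ||
               (!is.na(mantis[i]) && mantis[i] >= config$mantis)) {
      label[i] <- "MT-H"
    } else if (!is.na(sensor[i]) || !is.na(mantis[i])) {
      label[i] <- "MT-L"
    }
  }
  label
}
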