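#' The 96 trinucleotide substitution channels
#'
#' Channel names in the COSMIC SBS96 convention: pyrimidine-centered
#' substitutions `C>A, C>G, C>T, T>A, T>C, T>G`, each in the 16 flanking
#' contexts ordered A, C, G, T on both sides, written e.g. `"A[C>T]G"`.
#'
#' @return character vector of length 96.
#' @export
sbs96_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(bases, bases, function(u, d) {
      paste0(u, "[", s, "]", d)
    })))
  }))
}

#' Construct a trinucleotide substitution spectrum
#'
#' A 96-channel single-base-substitution frequency table, optionally with
#' simple 1-bp homopolymer insertion/deletion channels. SBS frequencies are
#' normalized to sum to 1; indel rates are interpreted as the fraction of all
#' gene events that are homopolymer insertions/deletions (so an indel rate of
#' 0.1 means 10% of simulated events are that indel type).
#'
#' @param freq named numeric vector of channel frequencies. Names must be a
#'   subset of [sbs96_contexts()]; missing channels get frequency 0.
#' @param indel_ins,indel_del 1-bp homopolymer insertion/deletion rates.
#' @param min_run minimum homopolymer run length hosting an indel (default 3).
#' @param id identifier carried into profiles built from this spectrum.
#' @return object of class `trinuc_spectrum`: list with `sbs` (named numeric,
#'   length 96, sums to 1), `indel` (list `ins`, `del`, `min_run`), `id`.
#' @export
#' @examples
#' sp <- trinuc_spectrum(c("A[C>T]G" = 1))
#' sum(sp$sbs)
trinuc_spectrum <- function(freq, indel_ins = 0, indel_del = 0, min_run = 3,
                            id = "custom") {
  channels <- sbs96_contexts()
  if (is.null(names(freq))) {
    if (length(freq) != 96L) {
      stop("unnamed frequency vector must have length 96 (COSMIC order)")
    }
    names(freq) <- channels
  }
  bad <- setdiff(names(freq), channels)
  if (length(bad)) {
    stop("unknown channel name(s): ", paste(head(bad, 3), collapse = ", "))
  }
  if (any(freq < 0) || any(!is.finite(freq))) {
    stop("channel frequencies must be finite and non-negative")
  }
  sbs <- setNames(numeric(96L), channels)
  sbs[names(freq)] <- freq
  if (sum(sbs) <= 0) stop("spectrum has zero total mass")
  sbs <- sbs / sum(sbs)
  stopifnot(indel_ins >= 0, indel_del >= 0, indel_ins + indel_del < 1)
  structure(
    list(
      sbs = sbs,
      indel = list(ins = indel_ins, del = indel_del, min_run = as.integer(min_run)),
      id = id
    ),
    class = "trinuc_spectrum"
  )
}

#' @export
print.trinuc_spectrum <- function(x, ...) {
  top <- sort(x$sbs, decreasing = TRUE)[1:3]
  cat(
    "<trinuc_spectrum> ", x$id, ": top channels ",
    paste(sprintf("%s=%.3f", names(top), top), collapse = ", "),
    if (x$indel$ins + x$indel$del > 0) {
      sprintf("; indels ins=%.3f del=%.3f", x$indel$ins, x$indel$del)
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Uniform substitution spectrum
#'
#' All 96 channels equally likely; useful as a no-signature baseline.
#'
#' @return `trinuc_spectrum`.
#' @export
uniform_spectrum <- function() {
  trinuc_spectrum(setNames(rep(1, 96), sbs96_contexts()), id = "uniform")
}

#' Synthetic colorectal-cancer-like spectrum
#'
#' A deterministic stand-in for a premixed CRC signature catalog, emulating
#' the dominant feature of colorectal tumors: clock-like deamination of
#' methylated CpG (SBS1), i.e. `N[C>T]G` channels, on top of a flat
#' background. This synthetic spectrum is used wherever the study's own
#' premixed 96-channel table would be; it reproduces the qualitative behavior
#' (strong CpG transition bias) without claiming its exact channel weights.
#'
#' @param cpg_weight total mass placed on the four `N[C>T]G` channels
#'   (default 0.5); the remainder is spread uniformly over all 96.
#' @param indel_ins,indel_del homopolymer indel rates (see
#'   [trinuc_spectrum()]); defaults 0.
#' @return `trinuc_spectrum` with id `"synthetic-crc"`.
#' @export
crc_spectrum <- function(cpg_weight = 0.5, indel_ins = 0, indel_del = 0) {
  stopifnot(cpg_weight >= 0, cpg_weight < 1)
  channels <- sbs96_contexts()
  w <- rep((1 - cpg_weight) / 96, 96)
  cpg <- grepl("\\[C>T\\]G$", channels)
  w[cpg] <- w[cpg] + cpg_weight / sum(cpg)
  trinuc_spectrum(setNames(w, channels),
    indel_ins = indel_ins, indel_del = indel_del,
    id = "synthetic-crc"
  )
}

#' Read a 96-channel spectrum from TSV
#'
#' Expects columns `context` (e.g. `"A[C>T]G"`) and `frequency`.
#'
#' @param path TSV file path.
#' @param id spectrum identifier (defaults to the file name).
#' @return `trinuc_spectrum`.
#' @export
read_spectrum_tsv <- function(path, id = basename(path)) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("context", "frequency")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("spectrum file missing required column(s): ", paste(miss, collapse = ", "))
  }
  trinuc_spectrum(setNames(tab$frequency, tab$context), id = id)
}

# Fold a coding-strand (up, ref, alt, down) context into its pyrimidine-
# centered SBS96 channel.  Purine-centered sites are reverse-complemented:
# flanks swap and all bases complement.  Vectorized.
fold_context <- function(up, ref, alt, down) {
  pur <- ref %in% c("A", "G")
  u <- ifelse(pur, complement_base(down), up)
  d <- ifelse(pur, complement_base(up), down)
  r <- ifelse(pur, complement_base(ref), ref)
  a <- ifelse(pur, complement_base(alt), alt)
  paste0(u, "[", r, ">", a, "]", d)
}

# Fold a single-base substitution into one of the 6 pyrimidine-centered
# classes C>A, C>G, C>T, T>A, T>C, T>G.  Vectorized.
fold_class6 <- function(ref, alt) {
  pur <- ref %in% c("A", "G")
  paste0(
    ifelse(pur, complement_base(ref), ref), ">",
    ifelse(pur, complement_base(alt), alt)
  )
}

#' Observed substitution spectrum of a mutation set
#'
#' Tallies single-nucleotide substitutions into the six pyrimidine-centered
#' classes, and insertions/deletions separately. Non-SNV records passed to
#' the SNV tally are skipped and counted.
#'
#' @param mutations mutation records ([load_cohort()] layout); should be
#'   restricted to one gene by the caller.
#' @return list with `snv` (named counts over C>A...T>G), `ins`, `del`
#'   (indel counts), and `skipped` (records that fit no category).
#' @export
observed_spectrum <- function(mutations) {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  snv <- setNames(integer(6L), classes)
  ins <- 0L
  del <- 0L
  skipped <- 0L
  if (nrow(mutations)) {
    ref <- toupper(as.character(mutations$ref))
    alt <- toupper(as.character(mutations$alt))
    is_snv <- !is.na(ref) & !is.na(alt) &
      ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & ref != alt
    is_ins <- !is.na(ref) & !is.na(alt) & (nchar(alt) > nchar(ref) | ref == "-")
    is_del <- !is.na(ref) & !is.na(alt) & (nchar(ref) > nchar(alt) | alt == "-")
    if (any(is_snv)) {
      tab <- table(factor(fold_class6(ref[is_snv], alt[is_snv]), levels = classes))
      snv <- setNames(as.integer(tab), classes)
    }
    ins <- sum(is_ins & !is_snv)
    del <- sum(is_del & !is_snv)
    skipped <- sum(!is_snv & !is_ins & !is_del)
  }
  list(snv = snv, ins = as.integer(ins), del = as.integer(del), skipped = as.integer(skipped))
}
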