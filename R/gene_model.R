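#' Build a coding-sequence gene model
#'
#' Wraps a coding-strand CDS plus one flanking base on each side, precomputes
#' the codon decomposition and translation, and validates the reading frame.
#' The flanking bases supply the trinucleotide context of the first and last
#' CDS positions; they are required rather than silently wrapped.
#'
#' A CDS may be supplied with or without its terminal stop codon. When the
#' last codon is a stop it is excluded from `protein_length` and carries no
#' mass in downstream mutability profiles (stop-gain at the natural stop is
#' not a coding change). An internal stop is an error; if the
#' reverse-complemented sequence would translate cleanly the error suggests a
#' strand check.
#'
#' @param cds coding-strand nucleotide string, length divisible by 3,
#'   alphabet ACGT.
#' @param symbol gene symbol.
#' @param flank5,flank3 single bases flanking the CDS 5' and 3'.
#' @return An object of class `gene_model`: list with `symbol`, `cds`,
#'   `flank5`, `flank3`, `n_codon` (codons in the CDS), `protein_length`
#'   (codons excluding a terminal stop), `codons`, `protein` (one-letter
#'   translation), `has_terminal_stop`.
#' @export
#' @examples
#' gm <- build_gene_model("ATGAAATAG", "TOY", flank5 = "C", flank3 = "G")
#' gm$protein_length  # 2: terminal stop excluded
build_gene_model <- function(cds, symbol, flank5 = "A", flank3 = "A") {
  cds <- toupper(cds)
  flank5 <- toupper(flank5)
  flank3 <- toupper(flank3)
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length (", nchar(cds), ") is not divisible by 3")
  }
  if (grepl("[^ACGT]", cds)) {
    stop("CDS contains ambiguous or non-ACGT bases")
  }
  if (nchar(flank5) != 1L || nchar(flank3) != 1L ||
      grepl("[^ACGT]", flank5) || grepl("[^ACGT]", flank3)) {
    stop("flank5/flank3 must each be a single ACGT base")
  }
  n_codon <- nchar(cds) / 3L
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  protein <- unname(Biostrings::GENETIC_CODE[codons])
  internal_stops <- which(protein[-n_codon] == "*")
  if (length(internal_stops)) {
    rc <- reverse_complement(cds)
    rc_codons <- substring(rc, seq(1L, nchar(rc), 3L), seq(3L, nchar(rc), 3L))
    rc_protein <- unname(Biostrings::GENETIC_CODE[rc_codons])
    hint <- if (!any(rc_protein[-length(rc_protein)] == "*")) {
      " (the reverse complement translates without internal stops; check the strand)"
    } else {
      ""
    }
    stop(
      "internal stop codon(s) at codon position(s) ",
      paste(internal_stops, collapse = ", "), hint
    )
  }
  has_terminal_stop <- protein[n_codon] == "*"
  structure(
    list(
      symbol = symbol,
      cds = cds,
      flank5 = flank5,
      flank3 = flank3,
      n_codon = n_codon,
      protein_length = n_codon - as.integer(has_terminal_stop),
      codons = codons,
      protein = protein,
      has_terminal_stop = has_terminal_stop
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(
    "<gene_model> ", x$symbol, ": ", nchar(x$cds), " nt, ",
    x$protein_length, " residues",
    if (x$has_terminal_stop) " (+ terminal stop)", "\n",
    sep = ""
  )
  invisible(x)
}
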