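#' Per-site mutation probabilities under a signature spectrum
#'
#' Maps every (CDS position, alternate base) pair onto its pyrimidine-centered
#' trinucleotide channel and assigns it a probability proportional to the
#' channel frequency, normalized over the whole gene. The result is the
#' probability of each possible single-base change conditional on exactly one
#' substitution occurring in the gene. The first and last CDS positions take
#' their flanking context from the gene model's flank bases. Sites inside a
#' terminal stop codon carry no mass.
#'
#' @param gene a [build_gene_model()] object.
#' @param spectrum a [trinuc_spectrum()].
#' @return Object of class `mutability_profile`: list with `gene` (symbol),
#'   `spectrum_id`, `n_codon` (coding codons, terminal stop excluded),
#'   `sites` — a data.frame with one row per (site, alt):
#'   `site` (1-based CDS position), `ref`, `alt`, `channel`, `codon`
#'   (1-based), `codon_pos` (1-3), `aa_ref`, `aa_alt`,
#'   `class` (`synonymous`/`missense`/`nonsense`), `p` (sums to 1).
#' @export
#' @examples
#' gm <- build_gene_model("ATGGAACGTAAA", "TOY", "C", "G")
#' prof <- site_mutability(gm, uniform_spectrum())
#' sum(prof$sites$p)
site_mutability <- function(gene, spectrum) {
  stopifnot(inherits(gene, "gene_model"), inherits(spectrum, "trinuc_spectrum"))
  L <- nchar(gene$cds)
  n_coding <- gene$protein_length
  L_model <- n_coding * 3L  # sites in a terminal stop codon excluded
  if (L_model < 3L) stop("gene model has no coding codons")
  full <- strsplit(paste0(gene$flank5, gene$cds, gene$flank3), "", fixed = TRUE)[[1]]
  site <- rep(seq_len(L_model), each = 3L)
  ref <- full[site + 1L]
  alts <- c("A", "C", "G", "T")
  alt <- unlist(lapply(ref[seq(1L, length(ref), 3L)], function(r) setdiff(alts, r)),
    use.names = FALSE
  )
  up <- full[site]
  down <- full[site + 2L]
  channel <- fold_context(up, ref, alt, down)
  p_raw <- unname(spectrum$sbs[channel])

  codon_idx <- (site - 1L) %/% 3L + 1L
  codon_pos <- (site - 1L) %% 3L + 1L
  ref_codon <- gene$codons[codon_idx]
  mut_codon <- ref_codon
  substr(mut_codon, codon_pos, codon_pos) <- alt
  aa_ref <- gene$protein[codon_idx]
  aa_alt <- unname(Biostrings::GENETIC_CODE[mut_codon])
  class <- ifelse(aa_alt == aa_ref, "synonymous",
    ifelse(aa_alt == "*", "nonsense", "missense")
  )
  total <- sum(p_raw)
  if (total <= 0) stop("spectrum assigns zero mass to every site of this gene")
  structure(
    list(
      gene = gene$symbol,
      spectrum_id = spectrum$id,
      n_codon = n_coding,
      sites = data.frame(
        site = site, ref = ref, alt = alt, channel = channel,
        codon = codon_idx, codon_pos = codon_pos,
        aa_ref = aa_ref, aa_alt = aa_alt, class = class,
        p = p_raw / total,
        stringsAsFactors = FALSE
      )
    ),
    class = "mutability_profile"
  )
}

#' @export
print.mutability_profile <- function(x, ...) {
  cat(
    "<mutability_profile> ", x$gene, " under ", x$spectrum_id, ": ",
    x$n_codon, " codons, ", nrow(x$sites), " (site,alt) pairs\n",
    sep = ""
  )
  invisible(x)
}

#' Aggregate a mutability profile to codon-level class probabilities
#'
#' Sums the per-(site, alt) probabilities within each codon by functional
#' class. Aggregates conserve total mass: across codons,
#' `p_syn + p_missense + p_truncating` sums to 1.
#'
#' @param profile a [site_mutability()] profile.
#' @return data.frame with one row per codon: `codon`, `aa_ref`, `p_syn`,
#'   `p_missense`, `p_truncating` (nonsense), `p_nonsyn`
#'   (missense + truncating), `p_total`.
#' @export
codon_profile <- function(profile) {
  stopifnot(inherits(profile, "mutability_profile"))
  s <- profile$sites
  codons <- seq_len(profile$n_codon)
  agg <- function(cls) {
    v <- numeric(profile$n_codon)
    rows <- s$class == cls
    if (any(rows)) {
      sums <- rowsum(s$p[rows], s$codon[rows])
      v[as.integer(rownames(sums))] <- sums[, 1]
    }
    v
  }
  p_syn <- agg("synonymous")
  p_mis <- agg("missense")
  p_trunc <- agg("nonsense")
  data.frame(
    codon = codons,
    aa_ref = s$aa_ref[match(codons, s$codon)],
    p_syn = p_syn,
    p_missense = p_mis,
    p_truncating = p_trunc,
    p_nonsyn = p_mis + p_trunc,
    p_total = p_syn + p_mis + p_trunc
  )
}

#' Rank codons by predicted mutation frequency
#'
#' Orders codons by their predicted frequency (nonsynonymous mass by default)
#' and reports frequencies relative to the top-ranked codon (rank 1 = 1.0,
#' the lollipop-plot convention). Ties break toward the lower codon index.
#'
#' @param codon_table output of [codon_profile()] or
#'   [corrected_codon_profile()].
#' @param k number of codons to return (silently truncated at the protein
#'   length).
#' @param mode `"nonsyn"` ranks by `p_nonsyn`, `"all"` by `p_total`.
#' @return data.frame `rank`, `codon`, `aa_ref`, `p`, `relative`
#'   (p / p\[rank 1\]).
#' @export
rank_predicted_hotspots <- function(codon_table, k = 5, mode = c("nonsyn", "all")) {
  mode <- match.arg(mode)
  stopifnot(k >= 1)
  col <- if (mode == "nonsyn" && "p_nonsyn" %in% names(codon_table)) {
    "p_nonsyn"
  } else if (mode == "all" && "p_total" %in% names(codon_table)) {
    "p_total"
  } else if ("p" %in% names(codon_table)) {
    "p"  # corrected profiles carry a single column
  } else {
    stop("codon_table lacks the required probability column")
  }
  v <- codon_table[[col]]
  ord <- order(-v, codon_table$codon)
  k <- min(k, nrow(codon_table))
  idx <- ord[seq_len(k)]
  data.frame(
    rank = seq_len(k),
    codon = codon_table$codon[idx],
    aa_ref = if ("aa_ref" %in% names(codon_table)) codon_table$aa_ref[idx] else NA_character_,
    p = v[idx],
    relative = v[idx] / v[ord[1]]
  )
}

#' Tally observed mutations per codon
#'
#' Helper shared by the hotspot and fit-comparison analyses: counts mutation
#' records per protein position, optionally restricted to given variant
#' classes.
#'
#' @param mutations mutation records with `protein_pos` and `variant_class`.
#' @param n_codon protein length (vector length of the result).
#' @param classes variant classes to count (default missense).
#' @return integer vector of length `n_codon`.
#' @export
observed_codon_counts <- function(mutations, n_codon,
                                  classes = "missense") {
  counts <- integer(n_codon)
  keep <- mutations$variant_class %in% classes & !is.na(mutations$protein_pos)
  pos <- mutations$protein_pos[keep]
  if (any(pos < 1 | pos > n_codon)) {
    stop("protein_pos outside 1..", n_codon)
  }
  if (length(pos)) {
    tab <- table(factor(pos, levels = seq_len(n_codon)))
    counts <- as.integer(tab)
  }
  counts
}
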