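# Shared fixtures, all generated in code.

# 4-codon toy gene without terminal stop: every codon is coding.
toy_gene <- function() {
  build_gene_model("ATGGAACGTAAA", "TOY", flank5 = "C", flank3 = "G")
}

# Exhaustive-enumeration oracle for site_mutability: walks every (site, alt)
# of the CDS by string manipulation, independent of the profile code path.
enumerate_profile_oracle <- function(cds, flank5, flank3, sbs) {
  full <- paste0(flank5, cds, flank3)
  code <- Biostrings::GENETIC_CODE
  comp <- function(x) chartr("ACGT", "TGCA", x)
  rows <- list()
  n_codon <- nchar(cds) / 3
  aa_last <- code[substr(cds, nchar(cds) - 2, nchar(cds))]
  coding_sites <- if (aa_last == "*") nchar(cds) - 3 else nchar(cds)
  for (i in seq_len(coding_sites)) {
    ref <- substr(full, i + 1, i + 1)
    up <- substr(full, i, i)
    down <- substr(full, i + 2, i + 2)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      ch <- if (ref %in% c("C", "T")) {
        paste0(up, "[", ref, ">", alt, "]", down)
      } else {
        paste0(comp(down), "[", comp(ref), ">", comp(alt), "]", comp(up))
      }
      ci <- (i - 1) %/% 3 + 1
      codon <- substr(cds, 3 * ci - 2, 3 * ci)
      mcodon <- codon
      substr(mcodon, (i - 1) %% 3 + 1, (i - 1) %% 3 + 1) <- alt
      rows[[length(rows) + 1]] <- data.frame(
        site = i, alt = alt, channel = ch, codon = ci,
        aa_ref = unname(code[codon]), aa_alt = unname(code[mcodon]),
        p_raw = unname(sbs[ch]), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p <- out$p_raw / sum(out$p_raw)
  out
}

# Minimal mutation-record data.frame with canonical columns.
make_mutations <- function(...) {
  args <- list(...)
  n <- if (length(args)) max(vapply(args, length, integer(1))) else 1L
  defaults <- list(
    sample_id = "s1", gene = "TOY", chrom = "chr1", pos = NA_real_,
    ref = NA_character_, alt = NA_character_, variant_class = "missense",
    protein_pos = NA_real_, aa_ref = NA_character_, aa_alt = NA_character_,
    allele_fraction = NA_real_, alteration_type = "mutation"
  )
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  as.data.frame(lapply(defaults, rep_len, n), stringsAsFactors = FALSE)
}

# Exact two-sided Fisher p by hypergeometric enumeration over all tables
# with the observed margins (probability-summation convention).
fisher_p_oracle <- function(a, b, c_, d) {
  m <- a + b
  n <- c_ + d
  k <- a + c_
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
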