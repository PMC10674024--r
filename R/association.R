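#' Assign driver-combination group labels
#'
#' Concatenates, in the fixed order A, P, B, K, the letters for mutated
#' *APC* (A), *TP53* (P), *BRAF* (B) and *KRAS* (K); tumors with none of the
#' four mutated are labelled `"N"`. Group labels use mutations only
#' (deletions excluded).
#'
#' @param apc,tp53,braf,kras logical vectors (mutation present).
#' @return character vector of group labels.
#' @export
#' @examples
#' assign_driver_group(TRUE, FALSE, FALSE, TRUE) # "AK"
assign_driver_group <- function(apc, tp53, braf, kras) {
  n <- length(apc)
  stopifnot(length(tp53) == n, length(braf) == n, length(kras) == n)
  m <- cbind(apc, tp53, braf, kras)
  if (anyNA(m)) stop("driver mutation calls must be non-missing")
  letters4 <- c("A", "P", "B", "K")
  out <- apply(m, 1, function(row) paste(letters4[row], collapse = ""))
  out[out == ""] <- "N"
  out
}

#' Build a sample-by-(gene, class) alteration matrix
#'
#' Converts mutation records into per-sample boolean alteration calls per
#' gene and class. Classes honor the hierarchy
#' `any` \eqn{\supseteq} `mutation_any` \eqn{\supseteq}
#' \{`mutation_LoF`, `mutation_WT`\}:
#' * `mutation_any`: any nonsynonymous mutation (missense, nonsense,
#'   frameshift, inframe indel, splice);
#' * `mutation_LoF` / `mutation_WT`: nonsense and frameshift mutations are
#'   LoF by definition; missense mutations are dichotomized with `scores`
#'   where given (records classified NA fall in neither);
#' * `homozygous_deletion`: records with that `alteration_type`;
#' * `any`: mutation or homozygous deletion.
#'
#' Column names are `GENE.class`, e.g. `PTEN.mutation_LoF`.
#'
#' @param mutations mutation records ([load_cohort()] layout).
#' @param samples sample records; the result has one row per sample, with
#'   `sample_id`, `subtype` (from `subtype_assigned`) and `stage` carried
#'   over.
#' @param genes genes to tabulate.
#' @param scores optional [functional_score_table()] for the LoF/WT split of
#'   missense records (applied to every gene present in the table's codons;
#'   in practice supply scores for the target gene only).
#' @param score_gene gene to which `scores` apply (default `"PTEN"`).
#' @param config see [somselect_config()].
#' @return data.frame alteration matrix.
#' @export
alteration_matrix <- function(mutations, samples, genes, scores = NULL,
                              score_gene = "PTEN",
                              config = somselect_config()) {
  ids <- samples$sample_id
  out <- data.frame(
    sample_id = ids,
    subtype = if ("subtype_assigned" %in% names(samples)) samples$subtype_assigned else "unknown",
    stage = if ("stage" %in% names(samples)) samples$stage else "unknown",
    stringsAsFactors = FALSE
  )
  nonsyn <- c("missense", "nonsense", "frameshift", "inframe_indel", "splice")
  for (g in genes) {
    rec <- mutations[mutations$gene == g, , drop = FALSE]
    is_mut <- rec$alteration_type == "mutation" & rec$variant_class %in% nonsyn
    mut_ids <- rec$sample_id[is_mut]
    del_ids <- rec$sample_id[rec$alteration_type == "homozygous_deletion"]
    lof_ids <- wt_ids <- character(0)
    if (!is.null(scores) && g == score_gene) {
      trunc <- is_mut & rec$variant_class %in% c("nonsense", "frameshift")
      mis <- is_mut & rec$variant_class == "missense" & !is.na(rec$protein_pos)
      cls <- rep(NA_character_, nrow(rec))
      if (any(mis)) {
        cls[mis] <- classify_function(
          rec$protein_pos[mis], rec$aa_alt[mis], scores, config
        )$class
      }
      lof_ids <- rec$sample_id[trunc | (!is.na(cls) & cls == "LoF")]
      wt_ids <- rec$sample_id[!is.na(cls) & cls == "WT"]
    }
    out[[paste0(g, ".mutation_any")]] <- ids %in% mut_ids
    out[[paste0(g, ".homozygous_deletion")]] <- ids %in% del_ids
    out[[paste0(g, ".any")]] <- ids %in% c(mut_ids, del_ids)
    if (!is.null(scores) && g == score_gene) {
      out[[paste0(g, ".mutation_LoF")]] <- ids %in% lof_ids
      out[[paste0(g, ".mutation_WT")]] <- ids %in% wt_ids
    }
  }
  out
}

#' Fisher co-occurrence / mutual-exclusivity test
#'
#' Two-sided Fisher exact test (summation of hypergeometric table
#' probabilities no greater than the observed table's) on the 2x2
#' presence/absence table of two alteration features, optionally within one
#' subtype stratum. The odds ratio is the sample OR with the
#' Haldane-Anscombe 0.5 correction when any cell is zero; its 95% CI is the
#' Wald interval on the log scale. The p-value always comes from the
#' uncorrected exact test. OR > 1 indicates co-occurrence, OR < 1 mutual
#' exclusivity, judged at the 0.005 significance convention.
#'
#' @param matrix an [alteration_matrix()].
#' @param a,b features as `c(gene, class)` character vectors, or bare column
#'   names.
#' @param stratum optional subtype label to restrict to.
#' @return object of class `contingency_result`: `table` (2x2),
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `untestable` (TRUE when a
#'   margin is degenerate, in which case OR/p are NA).
#' @export
test_cooccurrence <- function(matrix, a, b, stratum = NULL) {
  col_of <- function(f) {
    nm <- if (length(f) == 2) paste(f, collapse = ".") else f
    if (!nm %in% names(matrix)) stop("no such alteration column: ", nm)
    nm
  }
  if (!is.null(stratum)) {
    matrix <- matrix[matrix$subtype == stratum, , drop = FALSE]
    if (!nrow(matrix)) stop("stratum '", stratum, "' is empty")
  }
  x <- matrix[[col_of(a)]]
  y <- matrix[[col_of(b)]]
  tab <- table(factor(x, c(TRUE, FALSE)), factor(y, c(TRUE, FALSE)))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    res <- list(
      table = tab, odds_ratio = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, p_value = NA_real_, untestable = TRUE
    )
    return(structure(res, class = "contingency_result"))
  }
  ft <- fisher.test(tab)
  cells <- as.numeric(tab)  # a c b d in column order
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * qnorm(0.975) * se)
  structure(
    list(
      table = tab, odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
      p_value = ft$p.value, untestable = FALSE
    ),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  if (x$untestable) {
    cat("<contingency_result> untestable (degenerate margin)\n")
  } else {
    cat(
      "<contingency_result> OR = ", format(x$odds_ratio, digits = 3),
      " [", format(x$ci_low, digits = 3), ", ", format(x$ci_high, digits = 3),
      "], Fisher p = ", format(x$p_value, digits = 4), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Normalize allele fractions to a same-tumor driver mutation
#'
#' Elementwise ratio of the target mutation's allele fraction to the
#' reference driver mutation's in the same tumor; a clonality-normalized
#' scale on which purity and local copy number cancel to first order.
#'
#' @param af_target,af_reference numeric vectors in (0, 1\].
#' @return numeric vector of ratios.
#' @export
#' @examples
#' normalize_af(0.2, 0.4) # 0.5
normalize_af <- function(af_target, af_reference) {
  stopifnot(length(af_target) == length(af_reference))
  ok <- !is.na(af_target) & !is.na(af_reference)
  if (any(af_target[ok] <= 0 | af_target[ok] > 1) ||
      any(af_reference[ok] <= 0 | af_reference[ok] > 1)) {
    stop("allele fractions must lie in (0, 1]")
  }
  af_target / af_reference
}

#' Per-sample normalized allele fractions for a target gene
#'
#' Pairs every target-gene mutation with the same tumor's reference-driver
#' mutation of maximum allele fraction and returns the normalized ratios.
#' Tumors lacking a usable reference record are dropped, with the count
#' reported via a message.
#'
#' @param mutations mutation records.
#' @param target_gene gene whose mutations are normalized (default PTEN).
#' @param reference_genes driver genes supplying the reference AF.
#' @return data.frame `sample_id`, `protein_pos`, `variant_class`, `af`,
#'   `af_reference`, `normalized_af`.
#' @export
cohort_normalized_af <- function(mutations, target_gene = "PTEN",
                                 reference_genes = c("APC", "KRAS", "PIK3CA", "TP53")) {
  tg <- mutations[
    mutations$gene == target_gene & !is.na(mutations$allele_fraction) &
      mutations$alteration_type == "mutation", ,
    drop = FALSE
  ]
  ref <- mutations[
    mutations$gene %in% reference_genes & !is.na(mutations$allele_fraction) &
      mutations$allele_fraction > 0, ,
    drop = FALSE
  ]
  ref_max <- tapply(ref$allele_fraction, ref$sample_id, max)
  af_ref <- unname(ref_max[tg$sample_id])
  dropped <- sum(is.na(af_ref) | tg$allele_fraction <= 0)
  if (dropped) message(dropped, " target record(s) dropped: no usable reference AF")
  keep <- !is.na(af_ref) & tg$allele_fraction > 0
  data.frame(
    sample_id = tg$sample_id[keep],
    protein_pos = tg$protein_pos[keep],
    variant_class = tg$variant_class[keep],
    af = tg$allele_fraction[keep],
    af_reference = af_ref[keep],
    normalized_af = normalize_af(tg$allele_fraction[keep], af_ref[keep])
  )
}

#' Compare two allele-fraction distributions
#'
#' Two-sample Kolmogorov-Smirnov test; the exact small-sample p-value is
#' used when both groups have at most 25 observations, the asymptotic one
#' otherwise.
#'
#' @param group1,group2 numeric vectors (each length >= 2).
#' @return list `D` (KS statistic), `p_value`, `exact`.
#' @export
compare_af <- function(group1, group2) {
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  exact <- length(group1) <= 25 && length(group2) <= 25
  kt <- suppressWarnings(ks.test(group1, group2, exact = exact))
  list(D = unname(kt$statistic), p_value = kt$p.value, exact = exact)
}

#' Alteration frequency by stratum
#'
#' Frequencies of a target alteration across strata (e.g. combined stages
#' I+II versus III+IV within a subtype), each with a Wilson 95% interval,
#' plus a Fisher exact test of cross-stratum equality.
#'
#' @param matrix an [alteration_matrix()].
#' @param target feature as `c(gene, class)` or a bare column name.
#' @param stratum_col column of `matrix` defining strata.
#' @param strata optional subset/order of stratum values; defaults to the
#'   observed values.
#' @return list with `table` (data.frame `stratum`, `altered`, `total`,
#'   `frequency`, `ci_low`, `ci_high`) and `p_equal` (Fisher exact, NA when
#'   fewer than two nonempty strata).
#' @export
frequency_by_stratum <- function(matrix, target, stratum_col = "stage",
                                 strata = NULL) {
  nm <- if (length(target) == 2) paste(target, collapse = ".") else target
  if (!nm %in% names(matrix)) stop("no such alteration column: ", nm)
  if (!stratum_col %in% names(matrix)) stop("no such stratum column: ", stratum_col)
  sv <- as.character(matrix[[stratum_col]])
  if (is.null(strata)) strata <- sort(unique(sv[!is.na(sv) & sv != "unknown"]))
  rows <- lapply(strata, function(s) {
    sel <- sv == s
    total <- sum(sel)
    altered <- sum(matrix[[nm]][sel])
    if (total > 0) {
      ci <- wilson_ci(altered, total)
      data.frame(
        stratum = s, altered = altered, total = total,
        frequency = altered / total, ci_low = ci[1], ci_high = ci[2]
      )
    } else {
      data.frame(
        stratum = s, altered = 0L, total = 0L,
        frequency = NA_real_, ci_low = NA_real_, ci_high = NA_real_
      )
    }
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  nonempty <- tab$total > 0
  p_equal <- if (sum(nonempty) >= 2) {
    m <- rbind(tab$altered[nonempty], tab$total[nonempty] - tab$altered[nonempty])
    fisher.test(m)$p.value
  } else {
    NA_real_
  }
  list(table = tab, p_equal = p_equal)
}
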