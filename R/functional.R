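#' Assemble a functional score table
#'
#' Per-substitution functional measurements and annotations used to
#' dichotomize amino-acid changes as loss of function (LoF) or functionally
#' wild type (WT). Scores follow the deep-mutational-scanning convention of
#' this package's synthetic tables: higher = more functional, with LoF called
#' below the configured cutoff.
#'
#' @param scores data.frame with columns `codon`, `aa_alt`, `lpa`
#'   (lipid phosphatase activity score) and `abundance` (protein abundance
#'   score); either score may be NA.
#' @param annotations optional data.frame with columns `codon`, `aa_alt`,
#'   `call` in `pathogenic`/`benign` (clinical-database overrides).
#' @param indel_impact optional data.frame with columns `key` (caller-defined
#'   inframe-indel identifier) and `impact` in \[0, 1\] (1 = fully damaging).
#' @return object of class `functional_score_table`; `coverage` reports the
#'   fraction of scored substitutions among those listed.
#' @export
functional_score_table <- function(scores,
                                   annotations = NULL,
                                   indel_impact = NULL) {
  need <- c("codon", "aa_alt", "lpa", "abundance")
  miss <- setdiff(need, names(scores))
  if (length(miss)) stop("scores missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(scores$lpa) & !is.na(scores$lpa)) ||
      any(!is.finite(scores$abundance) & !is.na(scores$abundance))) {
    stop("scores must be finite or NA")
  }
  key <- paste(scores$codon, scores$aa_alt)
  if (anyDuplicated(key)) stop("duplicate (codon, aa_alt) entries in scores")
  ann <- NULL
  if (!is.null(annotations) && nrow(annotations)) {
    stopifnot(all(c("codon", "aa_alt", "call") %in% names(annotations)))
    if (!all(annotations$call %in% c("pathogenic", "benign"))) {
      stop("annotation call must be pathogenic or benign")
    }
    ann <- setNames(annotations$call, paste(annotations$codon, annotations$aa_alt))
  }
  ind <- NULL
  if (!is.null(indel_impact) && nrow(indel_impact)) {
    stopifnot(all(c("key", "impact") %in% names(indel_impact)))
    stopifnot(all(indel_impact$impact >= 0 & indel_impact$impact <= 1))
    ind <- setNames(indel_impact$impact, indel_impact$key)
  }
  structure(
    list(
      lpa = setNames(scores$lpa, key),
      abundance = setNames(scores$abundance, key),
      annotations = ann,
      indel_impact = ind,
      coverage = mean(!is.na(scores$lpa) | !is.na(scores$abundance))
    ),
    class = "functional_score_table"
  )
}

#' @export
print.functional_score_table <- function(x, ...) {
  cat(
    "<functional_score_table> ", length(x$lpa), " substitutions, coverage ",
    sprintf("%.1f%%", 100 * x$coverage), ", ",
    length(x$annotations), " annotations, ",
    length(x$indel_impact), " indel impacts\n",
    sep = ""
  )
  invisible(x)
}

#' Classify an amino-acid change as LoF, WT, or NA
#'
#' Evidence precedence: clinical-database annotation, then continuous scores
#' (LoF when the LPA score OR the abundance score falls below its cutoff; WT
#' when every available score clears its cutoff), then inframe-indel impact.
#' `NA` means no evidence channel fired.
#'
#' @param codon codon index (vectorized; ignored for indel keys).
#' @param aa_alt one-letter alternate amino acid (vectorized), or NA for an
#'   indel classified via `indel_key`.
#' @param scores a [functional_score_table()].
#' @param config cutoffs from [somselect_config()] (`lpa_cutoff`,
#'   `abundance_cutoff`, `indel_impact_cutoff`).
#' @param indel_key optional vector of inframe-indel keys, parallel to
#'   `codon`.
#' @return data.frame with columns `class` (`LoF`/`WT`/`NA`) and `evidence`
#'   (`annotation`/`lpa`/`abundance`/`scores`/`indel`/`none`).
#' @export
classify_function <- function(codon, aa_alt, scores,
                              config = somselect_config(),
                              indel_key = NULL) {
  stopifnot(inherits(scores, "functional_score_table"))
  n <- max(length(codon), length(aa_alt), length(indel_key %||% character(0)))
  codon <- rep_len(codon, n)
  aa_alt <- rep_len(aa_alt, n)
  if (!is.null(indel_key)) indel_key <- rep_len(indel_key, n)
  key <- paste(codon, aa_alt)
  cls <- rep("NA", n)
  ev <- rep("none", n)

  if (!is.null(scores$annotations)) {
    ann <- scores$annotations[key]
    hit <- !is.na(aa_alt) & !is.na(ann)
    cls[hit] <- ifelse(ann[hit] == "pathogenic", "LoF", "WT")
    ev[hit] <- "annotation"
  }
  open <- ev == "none" & !is.na(aa_alt)
  lpa <- unname(scores$lpa[key])
  ab <- unname(scores$abundance[key])
  lpa_lof <- !is.na(lpa) & lpa < config$lpa_cutoff
  ab_lof <- !is.na(ab) & ab < config$abundance_cutoff
  lof <- open & (lpa_lof | ab_lof)
  cls[lof] <- "LoF"
  ev[lof] <- ifelse(lpa_lof[lof], "lpa", "abundance")
  wt <- open & !lof & (!is.na(lpa) | !is.na(ab))
  cls[wt] <- "WT"
  ev[wt] <- "scores"

  if (!is.null(indel_key) && !is.null(scores$indel_impact)) {
    imp <- unname(scores$indel_impact[indel_key])
    hit <- ev == "none" & !is.na(imp)
    cls[hit] <- ifelse(imp[hit] >= config$indel_impact_cutoff, "LoF", "WT")
    ev[hit] <- "indel"
  }
  data.frame(class = cls, evidence = ev, stringsAsFactors = FALSE)
}

# Damaging indicator for the missense rows of a profile under a correction
# mode.  Nonsense changes are damaging under every mode.  Returns TRUE/FALSE/
# NA (NA = unscored under this mode).
damaging_under_mode <- function(sites, scores, mode, config) {
  key <- paste(sites$codon, sites$aa_alt)
  lpa <- unname(scores$lpa[key])
  ab <- unname(scores$abundance[key])
  out <- switch(mode,
    sign = rep(TRUE, nrow(sites)),
    lpa = lpa < config$lpa_cutoff,
    abund = ab < config$abundance_cutoff,
    `lpa+ab` = ifelse(is.na(lpa) & is.na(ab), NA,
      (!is.na(lpa) & lpa < config$lpa_cutoff) |
        (!is.na(ab) & ab < config$abundance_cutoff)
    ),
    lof = {
      cf <- classify_function(sites$codon, sites$aa_alt, scores, config)
      ifelse(cf$class == "NA", NA, cf$class == "LoF")
    },
    stop("unknown mode: ", mode)
  )
  out[sites$class == "nonsense"] <- TRUE
  out
}

#' Per-codon damage fractions
#'
#' For each codon, the signature-probability-weighted fraction of accessible
#' nonsynonymous substitutions that damage protein function under a given
#' evidence mode: `sign` (signature only, fraction identically 1), `lpa`,
#' `abund`, `lpa+ab` (either score below cutoff), or `lof` (full
#' classification including clinical annotations). Substitutions without a
#' score under the mode are excluded from both numerator and denominator by
#' default (`config$na_action = "exclude"`), or counted as functionally wild
#' type (`"wt"`).
#'
#' @param profile a [site_mutability()] profile.
#' @param scores a [functional_score_table()].
#' @param mode one of `sign`, `lpa`, `abund`, `lpa+ab`, `lof`.
#' @param config see [somselect_config()].
#' @return data.frame `codon`, `f_damage` (NA when the codon has no scored
#'   nonsynonymous mass), `mass_total` (nonsynonymous signature mass),
#'   `mass_scored`.
#' @export
damage_fraction <- function(profile, scores,
                            mode = c("sign", "lpa", "abund", "lpa+ab", "lof"),
                            config = somselect_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "mutability_profile"))
  s <- profile$sites[profile$sites$class %in% c("missense", "nonsense"), ]
  dmg <- damaging_under_mode(s, scores, mode, config)
  if (config$na_action == "wt") dmg[is.na(dmg)] <- FALSE
  scored <- !is.na(dmg)
  codons <- seq_len(profile$n_codon)
  sum_by_codon <- function(v, rows) {
    out <- numeric(profile$n_codon)
    if (any(rows)) {
      r <- rowsum(v[rows], s$codon[rows])
      out[as.integer(rownames(r))] <- r[, 1]
    }
    out
  }
  mass_total <- sum_by_codon(s$p, rep(TRUE, nrow(s)))
  mass_scored <- sum_by_codon(s$p, scored)
  mass_damaging <- sum_by_codon(s$p, scored & dmg)
  f <- ifelse(mass_scored > 0, mass_damaging / mass_scored, NA_real_)
  data.frame(
    codon = codons, f_damage = f,
    mass_total = mass_total, mass_scored = mass_scored
  )
}

#' Correct predicted codon frequencies for functional damage
#'
#' Multiplies each codon's predicted nonsynonymous frequency by its damage
#' fraction and renormalizes, yielding the prediction "mutations here must
#' also damage the protein". Mode `sign` returns the signature-only
#' prediction (renormalized nonsynonymous mass) unchanged. Codons whose
#' damage fraction is undefined keep the gene-wide mean fraction, so lack of
#' score coverage neither inflates nor deletes a codon.
#'
#' @param codon_table output of [codon_profile()].
#' @param damage output of [damage_fraction()] (ignored for mode `sign`).
#' @param mode correction mode (matching the `damage` input).
#' @return data.frame `codon`, `aa_ref`, `p` (sums to 1), `f_damage`.
#' @export
corrected_codon_profile <- function(codon_table, damage = NULL,
                                    mode = c("sign", "lpa", "abund", "lpa+ab", "lof")) {
  mode <- match.arg(mode)
  base <- codon_table$p_nonsyn
  if (sum(base) <= 0) stop("codon table has zero nonsynonymous mass")
  if (mode == "sign") {
    f <- rep(1, nrow(codon_table))
  } else {
    if (is.null(damage)) stop("damage fractions required for mode ", mode)
    stopifnot(nrow(damage) == nrow(codon_table))
    f <- damage$f_damage
    f[is.na(f)] <- mean(f, na.rm = TRUE)
  }
  p <- base * f
  if (sum(p) <= 0) stop("all codon frequencies zero after correction")
  data.frame(
    codon = codon_table$codon,
    aa_ref = codon_table$aa_ref,
    p = p / sum(p),
    f_damage = f
  )
}

#' Compare model fits to observed per-codon counts
#'
#' Chi-square-form distance between observed per-codon mutation counts and
#' each candidate prediction (signature-only and damage-corrected variants,
#' plus a uniform random baseline), with small-expectation pooling shared
#' with [spectrum_compare()]. Lower statistic = better fit.
#'
#' @param observed integer vector of observed counts per codon.
#' @param profiles named list of corrected codon profiles
#'   ([corrected_codon_profile()] outputs) or bare probability vectors.
#' @param include_rand add the uniform-over-codons baseline (default TRUE).
#' @param min_expected pooling threshold (see [somselect_config()]).
#' @return data.frame `mode`, `statistic`, `n_bins`, ordered as given
#'   (rand last).
#' @export
model_fit_comparison <- function(observed, profiles, include_rand = TRUE,
                                 min_expected = somselect_config()$min_expected) {
  n <- sum(observed)
  if (n <= 0) stop("no observed mutations")
  as_p <- function(x) {
    p <- if (is.data.frame(x)) x$p else x
    stopifnot(length(p) == length(observed))
    p / sum(p)
  }
  modes <- names(profiles)
  if (is.null(modes) || any(modes == "")) stop("profiles must be a named list")
  ps <- lapply(profiles, as_p)
  if (include_rand) {
    ps$rand <- rep(1 / length(observed), length(observed))
  }
  rows <- lapply(names(ps), function(m) {
    pooled <- pool_channels(observed, ps[[m]], n, min_expected = min_expected)
    dead <- pooled$p == 0
    stat <- if (any(dead & pooled$observed > 0)) {
      Inf  # the model forbids codons that were observed
    } else {
      pearson_stat(pooled$observed[!dead], pooled$p[!dead] / sum(pooled$p[!dead]), n)
    }
    data.frame(mode = m, statistic = stat, n_bins = sum(!dead))
  })
  do.call(rbind, rows)
}
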