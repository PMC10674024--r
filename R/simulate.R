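#' Generate a synthetic coding sequence
#'
#' A random CDS built from sense codons (no internal stop), with an optional
#' terminal stop codon and random single-base flanks. A synthetic stand-in
#' for a real gene's coding sequence, used throughout the test suite and the
#' worked examples.
#'
#' @param n_codons protein length in codons (default 403, the length of the
#'   motivating tumor suppressor).
#' @param seed RNG seed.
#' @param symbol gene symbol (default `"SYNGENE"`).
#' @param terminal_stop append a stop codon (default TRUE).
#' @return a [build_gene_model()] object.
#' @export
synthetic_gene <- function(n_codons = 403, seed = 1, symbol = "SYNGENE",
                           terminal_stop = TRUE) {
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  cds <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  if (terminal_stop) cds <- paste0(cds, sample(c("TAA", "TAG", "TGA"), 1))
  bases <- c("A", "C", "G", "T")
  build_gene_model(cds, symbol, flank5 = sample(bases, 1), flank3 = sample(bases, 1))
}

#' Generate synthetic functional scores and conservation
#'
#' Emulates a deep-mutational-scanning score table: each codon receives a
#' latent "importance" in \[0, 1\]; substitutions at important codons tend to
#' receive low LPA/abundance scores (damaging), and important codons also
#' receive low (i.e. constrained) conservation scores. Scores live on a 0-1
#' scale with wild-type-like activity near 1; the LoF cutoff in
#' [somselect_config()] is 0.5. A small fraction of substitutions carries a
#' clinical-style annotation consistent with its score; a configurable
#' fraction of scores is masked to NA to emulate incomplete coverage.
#'
#' @param gene a gene model.
#' @param seed RNG seed.
#' @param na_fraction fraction of substitutions with both scores missing
#'   (default 0.05, mirroring >90% coverage).
#' @param annotate_fraction fraction of substitutions given a database
#'   annotation (default 0.02).
#' @return list with `scores` (a [functional_score_table()]), `conservation`
#'   (per-residue score, lower = more constrained), `importance` (latent
#'   per-codon truth) and `damaging` (named logical truth per
#'   `codon aa_alt` key, from the LPA score against the default cutoff).
#' @export
synthetic_functional_data <- function(gene, seed = 1, na_fraction = 0.05,
                                      annotate_fraction = 0.02) {
  set.seed(seed)
  n <- gene$protein_length
  importance <- rbeta(n, 0.8, 0.8)
  aa <- setdiff(
    unique(unname(Biostrings::GENETIC_CODE[Biostrings::GENETIC_CODE != "*"])),
    NULL
  )
  grid <- expand.grid(codon = seq_len(n), aa_alt = aa, stringsAsFactors = FALSE)
  grid <- grid[grid$aa_alt != gene$protein[grid$codon], ]
  m <- nrow(grid)
  p_dmg <- 0.15 + 0.7 * importance[grid$codon]
  dmg <- runif(m) < p_dmg
  draw <- function(is_dmg) {
    ifelse(is_dmg, rbeta(m, 2, 8), rbeta(m, 8, 2))
  }
  lpa <- draw(dmg)
  abundance <- draw(dmg & (runif(m) < 0.7))  # abundance loss in a subset
  mask <- runif(m) < na_fraction
  lpa[mask] <- NA
  abundance[mask] <- NA
  ann_idx <- which(runif(m) < annotate_fraction)
  annotations <- if (length(ann_idx)) {
    data.frame(
      codon = grid$codon[ann_idx], aa_alt = grid$aa_alt[ann_idx],
      call = ifelse(dmg[ann_idx], "pathogenic", "benign")
    )
  } else {
    NULL
  }
  conservation <- round(2 * (1 - importance) - 1 + rnorm(n, 0, 0.15), 3)
  list(
    scores = functional_score_table(
      data.frame(grid, lpa = lpa, abundance = abundance),
      annotations = annotations
    ),
    conservation = conservation,
    importance = importance,
    damaging = setNames(
      !is.na(lpa) & lpa < somselect_config()$lpa_cutoff,
      paste(grid$codon, grid$aa_alt)
    )
  )
}

#' Generate synthetic structure models
#'
#' A compact self-avoiding-ish random walk at ~3.8 angstrom steps stands in
#' for a folded backbone; each of `n_models` models adds independent
#' coordinate noise, emulating the variation among top-ranked predicted
#' structure models. Each residue carries `atoms_per_residue` atoms jittered
#' around its center.
#'
#' @param n_residues chain length.
#' @param seed RNG seed.
#' @param n_models number of models (default 5).
#' @param atoms_per_residue atoms per residue (default 3).
#' @param noise per-model coordinate noise sd in angstrom (default 0.4).
#' @return list of atom data.frames (columns `residue`, `x`, `y`, `z`), one
#'   per model.
#' @export
synthetic_structure <- function(n_residues, seed = 1, n_models = 5,
                                atoms_per_residue = 3, noise = 0.4) {
  set.seed(seed)
  # biased random walk that keeps folding back toward the origin
  pos <- matrix(0, n_residues, 3)
  for (i in 2:n_residues) {
    step <- rnorm(3)
    pull <- -pos[i - 1, ] * 0.02
    dirv <- step + pull
    pos[i, ] <- pos[i - 1, ] + 3.8 * dirv / sqrt(sum(dirv^2))
  }
  lapply(seq_len(n_models), function(m) {
    p <- pos + matrix(rnorm(length(pos), 0, noise), ncol = 3)
    data.frame(
      residue = rep(seq_len(n_residues), each = atoms_per_residue),
      x = rep(p[, 1], each = atoms_per_residue) + rnorm(n_residues * atoms_per_residue, 0, 0.8),
      y = rep(p[, 2], each = atoms_per_residue) + rnorm(n_residues * atoms_per_residue, 0, 0.8),
      z = rep(p[, 3], each = atoms_per_residue) + rnorm(n_residues * atoms_per_residue, 0, 0.8)
    )
  })
}

#' Pick a synthetic interface residue set
#'
#' A contiguous block of residues standing in for a dimer interface.
#'
#' @param n_residues protein length.
#' @param size interface size (default 30).
#' @param start first residue (default places the block mid-chain).
#' @return integer vector of residue indices.
#' @export
synthetic_interface <- function(n_residues, size = 30,
                                start = max(1L, n_residues %/% 3)) {
  stopifnot(start + size - 1 <= n_residues)
  seq.int(start, start + size - 1L)
}

#' Simulation configuration
#'
#' Defaults encode the study conditions of the motivating large
#' colorectal-cancer cohort: subtype mixture 94.6% MT-L / 4.7% MT-H / 0.7%
#' MSS-htmb; log-normal TMB within the subtype-defining windows; target-gene
#' alteration probabilities 3.9% / 18.1% / 44% by subtype; an SBS1-like CpG
#' transition spectrum, deletion-skewed homopolymer indels in MT-H and
#' insertion-skewed in MT-L; driver-gene marginal frequencies typical of
#' colorectal tumors with pairwise dependence expressed as log odds ratios.
#'
#' @param n_tumors cohort size.
#' @param ... overrides for any default entry (unknown names are an error).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tumors = 1000, ...) {
  cfg <- list(
    n_tumors = n_tumors,
    subtype_props = c("MT-L" = 0.946, "MT-H" = 0.047, "MSS-htmb" = 0.007),
    # meanlog/sdlog per subtype; medians ~5, ~35, ~140 mut/Mb
    tmb_lognormal = list(
      "MT-L" = c(meanlog = log(5), sdlog = 0.5),
      "MT-H" = c(meanlog = log(35), sdlog = 0.35),
      "MSS-htmb" = c(meanlog = log(140), sdlog = 0.15)
    ),
    spectra = list(
      "MT-L" = crc_spectrum(cpg_weight = 0.5, indel_ins = 0.03, indel_del = 0.015),
      "MT-H" = crc_spectrum(cpg_weight = 0.35, indel_ins = 0.02, indel_del = 0.12),
      "MSS-htmb" = crc_spectrum(cpg_weight = 0.2)
    ),
    gene_mut_prob = c("MT-L" = 0.039, "MT-H" = 0.181, "MSS-htmb" = 0.44),
    gene_del_prob = c("MT-L" = 0.025, "MT-H" = 0.005, "MSS-htmb" = 0.005),
    truncating_omega = 1,
    nontruncating_omega = 1,
    damage_linked = FALSE,
    interface = NULL,
    depletion_factor = 1,
    driver_marginals = c(
      APC = 0.70, TP53 = 0.60, KRAS = 0.45, BRAF = 0.10,
      PIK3CA = 0.15, SMAD4 = 0.10
    ),
    driver_log_ors = data.frame(
      gene_a = character(0), gene_b = character(0), log_or = numeric(0)
    ),
    af = list(
      clonal_shape1 = 14, clonal_shape2 = 26,     # clonal AF ~ 0.35
      subclonal_shape1 = 4, subclonal_shape2 = 36, # subclonal AF ~ 0.10
      subclonal_fraction = 0.25
    ),
    stage_probs = c(I = 0.15, II = 0.25, III = 0.3, IV = 0.2, unknown = 0.1),
    ms_known_fraction = 0.5
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) stop("unknown sim_config entries: ", paste(unknown, collapse = ", "))
    # entries are replaced wholesale (no deep merge), so data.frame-valued
    # entries like driver_log_ors behave predictably
    for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  }
  stopifnot(abs(sum(cfg$subtype_props) - 1) < 1e-8)
  stopifnot(cfg$truncating_omega > 0, cfg$nontruncating_omega > 0)
  stopifnot(cfg$depletion_factor >= 1)
  structure(cfg, class = "sim_config")
}

# Joint distribution over driver genotypes matching marginals and pairwise
# (marginal) odds ratios by iterative proportional fitting on the 2^k table.
fit_driver_joint <- function(marginals, log_ors, max_iter = 500, tol = 1e-10) {
  genes <- names(marginals)
  k <- length(genes)
  cells <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  colnames(cells) <- genes
  p <- rep(1 / nrow(cells), nrow(cells))

  pair_targets <- list()
  if (nrow(log_ors)) {
    for (r in seq_len(nrow(log_ors))) {
      ga <- log_ors$gene_a[r]
      gb <- log_ors$gene_b[r]
      if (!ga %in% genes || !gb %in% genes) {
        stop("log-OR names unknown gene pair (", ga, ", ", gb, ")")
      }
      pa <- marginals[[ga]]
      pb <- marginals[[gb]]
      psi <- exp(log_ors$log_or[r])
      p11 <- if (abs(psi - 1) < 1e-12) {
        pa * pb
      } else {
        s <- 1 + (psi - 1) * (pa + pb)
        disc <- s^2 - 4 * psi * (psi - 1) * pa * pb
        if (disc < 0) stop("infeasible log-OR/marginal combination for pair (", ga, ", ", gb, ")")
        (s - sqrt(disc)) / (2 * (psi - 1))
      }
      if (p11 <= max(0, pa + pb - 1) || p11 >= min(pa, pb)) {
        stop("infeasible log-OR/marginal combination for pair (", ga, ", ", gb, ")")
      }
      pair_targets[[r]] <- list(
        a = ga, b = gb,
        target = c(`11` = p11, `10` = pa - p11, `01` = pb - p11, `00` = 1 - pa - pb + p11)
      )
    }
  }
  for (iter in seq_len(max_iter)) {
    p_old <- p
    for (g in genes) {
      cur <- sum(p[cells[, g] == 1])
      p[cells[, g] == 1] <- p[cells[, g] == 1] * marginals[[g]] / cur
      p[cells[, g] == 0] <- p[cells[, g] == 0] * (1 - marginals[[g]]) / (1 - cur)
    }
    for (pt in pair_targets) {
      idx <- paste0(cells[, pt$a], cells[, pt$b])
      cur <- tapply(p, idx, sum)
      scale <- pt$target[c("11", "10", "01", "00")] /
        cur[c("11", "10", "01", "00")]
      p <- p * scale[match(idx, c("11", "10", "01", "00"))]
    }
    if (max(abs(p - p_old)) < tol) break
  }
  list(cells = cells, p = p / sum(p))
}

#' Simulate mutations in a gene under selection
#'
#' Places `n` mutation events on a gene by weighted sampling from the
#' signature-based mutability profile (acceptance-resampling: weights are
#' applied to the profile and renormalized, so the realized count is exactly
#' `n`). Weights implement:
#' * class selection: nonsense events weighted by `omega_truncating`,
#'   missense by `omega_nontruncating` (synonymous weight 1);
#' * damage linkage: with `damage_linked` and a score table, the
#'   non-truncating multiplier applies only to LoF-classified missense
#'   changes (others keep weight 1);
#' * interface depletion: events in interface codons divided by
#'   `depletion_factor`.
#'
#' When the spectrum carries homopolymer indel rates, the corresponding
#' fraction of events becomes 1-bp insertion/deletion frameshift records at
#' homopolymer runs of at least `min_run` bases.
#'
#' @param gene a gene model.
#' @param spectrum a [trinuc_spectrum()].
#' @param n number of mutation events (>= 0).
#' @param omega_truncating,omega_nontruncating class selection multipliers.
#' @param damage optional [functional_score_table()] (with `damage_linked`).
#' @param damage_linked restrict the non-truncating multiplier to
#'   LoF-classified changes.
#' @param interface optional residue indices under depletion.
#' @param depletion_factor fold reduction inside the interface (>= 1).
#' @param sample_ids optional vector of sample ids, recycled to `n`.
#' @param af_par allele-fraction model (see [sim_config()]'s `af` entry);
#'   NULL leaves `allele_fraction` NA.
#' @param seed optional seed; NULL continues the current RNG stream.
#' @param profile optional precomputed [site_mutability()] profile.
#' @param config cutoffs for the damage linkage.
#' @return mutation records data.frame ([load_cohort()] layout) with truth
#'   columns `sim_class`, `sim_damaging`, `sim_clonal`.
#' @export
simulate_gene_mutations <- function(gene, spectrum, n,
                                    omega_truncating = 1,
                                    omega_nontruncating = 1,
                                    damage = NULL, damage_linked = FALSE,
                                    interface = NULL, depletion_factor = 1,
                                    sample_ids = NULL, af_par = NULL,
                                    seed = NULL, profile = NULL,
                                    config = somselect_config()) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(profile)) profile <- site_mutability(gene, spectrum)
  s <- profile$sites
  w <- rep(1, nrow(s))
  w[s$class == "nonsense"] <- omega_truncating
  if (damage_linked && !is.null(damage)) {
    mis <- s$class == "missense"
    dmg <- damaging_under_mode(s[mis, ], damage, "lpa", config)
    dmg[is.na(dmg)] <- FALSE
    w[mis][dmg] <- omega_nontruncating
  } else {
    w[s$class == "missense"] <- omega_nontruncating
  }
  if (!is.null(interface) && depletion_factor > 1) {
    if (inherits(interface, "residue_set")) interface <- interface$residues
    w[s$codon %in% interface] <- w[s$codon %in% interface] / depletion_factor
  }
  wp <- w * s$p
  if (sum(wp) <= 0) stop("all acceptance weights are zero")

  n_indel <- 0L
  indel_rec <- NULL
  id <- spectrum$indel
  if (n > 0 && (id$ins + id$del) > 0) {
    n_indel <- rbinom(1, n, id$ins + id$del)
    if (n_indel > 0) {
      runs <- homopolymer_runs(gene$cds, id$min_run)
      if (!nrow(runs)) {
        n_indel <- 0L
      } else {
        ridx <- sample.int(nrow(runs), n_indel, replace = TRUE, prob = runs$length)
        is_ins <- runif(n_indel) < id$ins / (id$ins + id$del)
        pos <- runs$start[ridx]
        base <- runs$base[ridx]
        indel_rec <- data.frame(
          pos = pos,
          ref = ifelse(is_ins, base, paste0(base, base)),
          alt = ifelse(is_ins, paste0(base, base), base),
          protein_pos = (pos - 1L) %/% 3L + 1L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  n_snv <- n - n_indel
  rows <- if (n_snv > 0) {
    sample.int(nrow(s), n_snv, replace = TRUE, prob = wp)
  } else {
    integer(0)
  }

  cls_snv <- s$class[rows]
  dmg_snv <- if (!is.null(damage)) {
    out <- rep(NA, length(rows))
    mis <- cls_snv == "missense"
    if (any(mis)) {
      d <- damaging_under_mode(s[rows[mis], ], damage, "lpa", config)
      out[mis] <- d
    }
    out[cls_snv == "nonsense"] <- TRUE
    out[cls_snv == "synonymous"] <- FALSE
    out
  } else {
    cls_snv == "nonsense"
  }

  rec <- data.frame(
    sample_id = NA_character_,
    gene = gene$symbol,
    chrom = "chrS",
    pos = c(s$site[rows], if (!is.null(indel_rec)) indel_rec$pos),
    ref = c(s$ref[rows], if (!is.null(indel_rec)) indel_rec$ref),
    alt = c(s$alt[rows], if (!is.null(indel_rec)) indel_rec$alt),
    variant_class = c(
      ifelse(cls_snv == "nonsense", "nonsense",
        ifelse(cls_snv == "synonymous", "synonymous", "missense")
      ),
      rep("frameshift", n_indel)
    ),
    protein_pos = c(s$codon[rows], if (!is.null(indel_rec)) indel_rec$protein_pos),
    aa_ref = c(s$aa_ref[rows], rep(NA_character_, n_indel)),
    aa_alt = c(s$aa_alt[rows], rep(NA_character_, n_indel)),
    allele_fraction = NA_real_,
    alteration_type = "mutation",
    sim_class = c(cls_snv, rep("frameshift", n_indel)),
    sim_damaging = c(dmg_snv, rep(TRUE, n_indel)),
    sim_clonal = NA,
    stringsAsFactors = FALSE
  )
  if (nrow(rec)) {
    if (!is.null(sample_ids)) rec$sample_id <- rep_len(sample_ids, nrow(rec))
    if (!is.null(af_par)) {
      clonal <- runif(nrow(rec)) >= af_par$subclonal_fraction
      rec$sim_clonal <- clonal
      rec$allele_fraction <- ifelse(
        clonal,
        rbeta(nrow(rec), af_par$clonal_shape1, af_par$clonal_shape2),
        rbeta(nrow(rec), af_par$subclonal_shape1, af_par$subclonal_shape2)
      )
    }
  }
  rec
}

# Homopolymer runs of length >= min_run: data.frame(start, length, base).
homopolymer_runs <- function(cds, min_run = 3) {
  x <- strsplit(cds, "", fixed = TRUE)[[1]]
  r <- rle(x)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_run
  data.frame(
    start = (ends - r$lengths + 1L)[keep],
    length = r$lengths[keep],
    base = r$values[keep],
    stringsAsFactors = FALSE
  )
}

#' Simulate a tumor cohort with known ground truth
#'
#' Draws, for each tumor: a microsatellite subtype, a TMB from the subtype's
#' log-normal, a driver genotype from the joint distribution matching the
#' configured marginals and pairwise log odds ratios (iterative proportional
#' fitting), panel features (mutation count, CNA fraction, MMR mutation
#' status) consistent with the subtype, a stage, and target-gene mutation/
#' deletion events placed by [simulate_gene_mutations()] under the
#' configured selection, damage linkage and interface depletion. Allele
#' fractions follow the clonal/subclonal Beta mixture. Fully reproducible:
#' the same `(config, seed)` pair regenerates the identical cohort.
#'
#' @param config a [sim_config()].
#' @param gene gene model for the target gene (default
#'   `synthetic_gene(403)`).
#' @param functional optional [synthetic_functional_data()] bundle for
#'   damage-linked selection.
#' @param seed RNG seed (default 1).
#' @return list with `mutations`, `samples` (canonical [load_cohort()]
#'   layouts; truth columns `sim_*` on mutations, `sim_subtype` on samples)
#'   and `truth` (implanted parameters, driver joint, seed).
#' @export
simulate_cohort <- function(config = sim_config(), gene = NULL,
                            functional = NULL, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(gene)) gene <- synthetic_gene(403, seed = 1)
  set.seed(seed)  # after gene construction, which uses its own seed
  n <- config$n_tumors
  subtypes <- names(config$subtype_props)
  subtype <- sample(subtypes, n, replace = TRUE, prob = config$subtype_props)
  tmb <- vapply(subtype, function(st) {
    par <- config$tmb_lognormal[[st]]
    rlnorm(1, par["meanlog"], par["sdlog"])
  }, numeric(1), USE.NAMES = FALSE)

  joint <- fit_driver_joint(as.list(config$driver_marginals), config$driver_log_ors)
  cell_idx <- sample.int(nrow(joint$cells), n, replace = TRUE, prob = joint$p)
  genotype <- joint$cells[cell_idx, , drop = FALSE] == 1

  mmr <- runif(n) < ifelse(subtype == "MT-H", 0.7, 0.05)
  cna <- rbeta(n, ifelse(subtype == "MT-H", 1.2, 3), ifelse(subtype == "MT-H", 6, 5))
  mutation_count <- rpois(n, tmb * 1.2) # ~1.2 Mb panel footprint
  stage <- sample(names(config$stage_probs), n, replace = TRUE, prob = config$stage_probs)
  ms_known <- ifelse(
    runif(n) < config$ms_known_fraction,
    ifelse(subtype == "MT-H", "MSI-H", "MSS"),
    "unknown"
  )
  ids <- sprintf("T%05d", seq_len(n))

  samples <- data.frame(
    sample_id = ids,
    ms_status_known = ms_known,
    tmb = tmb,
    sensor_score = NA_real_,
    mantis_score = NA_real_,
    panel_id = "SIMPANEL",
    cna_fraction = cna,
    mmr_mutated = mmr,
    mutation_count = mutation_count,
    stage = stage,
    subtype_assigned = "unknown",
    sim_subtype = subtype,
    stringsAsFactors = FALSE
  )

  # target-gene events, simulated per subtype so each subtype keeps its
  # spectrum, then assigned to the flagged tumors
  mutated <- runif(n) < unname(config$gene_mut_prob[subtype])
  mut_list <- list()
  for (st in subtypes) {
    carriers <- ids[mutated & subtype == st]
    if (!length(carriers)) next
    mut_list[[st]] <- simulate_gene_mutations(
      gene, config$spectra[[st]], length(carriers),
      omega_truncating = config$truncating_omega,
      omega_nontruncating = config$nontruncating_omega,
      damage = if (!is.null(functional)) functional$scores else NULL,
      damage_linked = config$damage_linked,
      interface = config$interface,
      depletion_factor = config$depletion_factor,
      sample_ids = carriers,
      af_par = config$af
    )
  }
  gene_mut <- if (length(mut_list)) do.call(rbind, mut_list) else NULL

  deleted <- !mutated & runif(n) < unname(config$gene_del_prob[subtype])
  del_rec <- if (any(deleted)) {
    data.frame(
      sample_id = ids[deleted], gene = gene$symbol, chrom = "chrS",
      pos = NA_real_, ref = NA_character_, alt = NA_character_,
      variant_class = "other", protein_pos = NA_real_,
      aa_ref = NA_character_, aa_alt = NA_character_,
      allele_fraction = NA_real_, alteration_type = "homozygous_deletion",
      sim_class = "deletion", sim_damaging = TRUE, sim_clonal = NA,
      stringsAsFactors = FALSE
    )
  } else {
    NULL
  }

  driver_rec <- local({
    recs <- list()
    for (g in colnames(genotype)) {
      carriers <- ids[genotype[, g]]
      if (!length(carriers)) next
      clonal <- runif(length(carriers)) >= config$af$subclonal_fraction * 0.4
      recs[[g]] <- data.frame(
        sample_id = carriers, gene = g, chrom = "chrD",
        pos = NA_real_, ref = NA_character_, alt = NA_character_,
        variant_class = "missense", protein_pos = NA_real_,
        aa_ref = NA_character_, aa_alt = NA_character_,
        allele_fraction = ifelse(
          clonal,
          rbeta(length(carriers), config$af$clonal_shape1, config$af$clonal_shape2),
          rbeta(length(carriers), config$af$subclonal_shape1, config$af$subclonal_shape2)
        ),
        alteration_type = "mutation",
        sim_class = "driver", sim_damaging = TRUE, sim_clonal = clonal,
        stringsAsFactors = FALSE
      )
    }
    if (length(recs)) do.call(rbind, recs) else NULL
  })

  mutations <- do.call(rbind, Filter(Negate(is.null), list(gene_mut, del_rec, driver_rec)))
  rownames(mutations) <- NULL
  list(
    mutations = mutations,
    samples = samples,
    truth = list(
      seed = seed,
      subtype = setNames(subtype, ids),
      truncating_omega = config$truncating_omega,
      nontruncating_omega = config$nontruncating_omega,
      damage_linked = config$damage_linked,
      interface = config$interface,
      depletion_factor = config$depletion_factor,
      driver_log_ors = config$driver_log_ors,
      driver_joint = joint
    )
  )
}
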