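---
title: "Methods: signature-aware selection analysis of somatic mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-aware selection analysis of somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somselect)
```

# The scientific question

When a tumor suppressor such as *PTEN* is recurrently mutated in a cancer
cohort, two very different forces shape where those mutations land. The DNA
itself is not uniformly mutable: mutational processes (spontaneous
deamination of methylated CpG, mismatch-repair failure, polymerase
proofreading defects) each prefer particular bases in particular
trinucleotide contexts. On top of that, tumors are under selection: changes
that destroy the protein's function are retained and expand, changes that do
not are mostly passengers. `somselect` separates these two forces. It builds
a *background mutability model* from a 96-channel substitution spectrum,
asks how far the observed mutation pattern departs from it, and then asks
how much of the departure is explained by *protein-level damage* — measured
by deep-mutational-scanning scores for lipid phosphatase activity (LPA) and
protein abundance, clinical-database annotations, and structure-based
statistics (3D hotspots, dimer-interface coldspots).

# The background mutability model

A gene is represented as its coding-strand CDS with one flanking base on
each side (`build_gene_model()`). A CDS may include its terminal stop codon;
if so, the stop is excluded from the protein length and carries no model
mass, since stop-codon changes are not comparable coding events. An internal
stop is rejected outright, with a strand-check hint when the reverse
complement would translate cleanly.

The spectrum (`trinuc_spectrum()`) is a premixed 96-channel table in the
COSMIC SBS96 convention: pyrimidine-centered substitutions with both
flanking bases. Purine-centered coding-strand sites are folded onto their
channel by reverse complement (flanks swap and complement). We deliberately
take the spectrum as a single premixed table rather than refitting signature
mixtures per cohort: signature refitting is a separate, well-served problem,
and the analyses here only need the resulting channel frequencies.

`site_mutability()` assigns every (CDS site, alternate base) pair the
frequency of its channel and normalizes over the gene, yielding the
probability of each specific change *conditional on one substitution
occurring in the gene*. Aggregation to codons (`codon_profile()`) splits
each codon's mass into synonymous, missense and truncating (nonsense)
classes by applying each substitution to its codon under the standard
genetic code; mass is conserved exactly (sums to 1 within 1e-9). Predicted
hotspots are codons ranked by nonsynonymous mass, reported relative to the
top-ranked codon (the lollipop-plot convention); ties break toward the lower
codon index so results are deterministic.

Indels are handled deliberately minimally: the spectrum can carry 1-bp
homopolymer insertion/deletion rates (runs of at least 3 bases by default),
which is enough to emulate the deletion-skew of mismatch-repair-deficient
tumors and the opposite skew of stable tumors. The full indel taxonomy is
out of scope; consequently frameshift records cannot be benchmarked against
the substitution profile and are excluded from truncating dN/dS (with a
message) whenever the profile has no indel mass.

# Departure tests ("modified chi-square")

All observed-versus-expected comparisons use the same construction
(`spectrum_compare()`): a Pearson chi-square-form statistic whose reference
distribution is obtained by multinomial Monte-Carlo resampling under the
expected proportions, not from the asymptotic chi-square. Channels whose
expected count falls below 5 are pooled into a residual bin before the
statistic is computed, and the identical pooling applies to every replicate.
Monte-Carlo p-values are add-one corrected, `(1 + #{sim >= obs})/(n_mc + 1)`,
so the smallest reportable p at 999 replicates is 1/1000. The same machinery
drives the synonymous-placement test (`synonymous_deviation_test()`), which
probes DNA-level processes beyond the signature model using mutations that
cannot be under protein-level selection: synthetic synonymous count vectors
are drawn from the profile's synonymous mass and the observed vector's
distance to expectation is ranked among them.

# Functional correction and dN/dS

Amino-acid changes are dichotomized (`classify_function()`) with a strict
evidence precedence: clinical-database annotation first, then continuous
scores (loss of function when the LPA *or* the abundance score falls below
its cutoff), then inframe-indel impact scores; `NA` when nothing fires. The
score cutoffs are configuration constants (0.5 on the 0–1 synthetic score
scale, wild-type near 1) because published score sets calibrate their own
dichotomization points; users supplying real score tables should override
them via `somselect_config()`.

`damage_fraction()` computes, per codon, the signature-probability-weighted
fraction of accessible nonsynonymous changes that are damaging under a
chosen evidence mode (`sign`, `lpa`, `abund`, `lpa+ab`, `lof`). Unscored
substitutions are excluded from numerator and denominator by default rather
than counted as functionally wild type, to avoid diluting the fraction
toward zero wherever coverage is thin; the alternative is a configuration
switch. `corrected_codon_profile()` multiplies predicted codon frequencies
by these fractions and renormalizes; codons with no scored mass keep the
gene-wide mean fraction so missing coverage neither deletes nor inflates
them. `model_fit_comparison()` then scores each candidate prediction
(including a uniform `rand` baseline) against observed counts with the
shared pooled chi-square form.

dN/dS (`estimate_dnds()`) is the directly calculated benchmark form: the
observed nonsynonymous-to-synonymous count ratio divided by the ratio of the
profile's class mass to its synonymous mass. Normalizing by the
signature-derived expected ratio (rather than raw site counts) is the point
of the construction — it removes the spectrum's nucleotide preferences from
the selection estimate; a raw-count comparison can be had by building the
profile from a uniform spectrum. The 95% interval is the exact conditional
one: given `N + S`, `N` is binomial with success probability
`wE/(1 + wE)`, so a Clopper–Pearson interval for that probability maps
monotonically onto an interval for `w`. We chose it over the log-ratio
normal approximation after measuring the latter's coverage at 92% for
`w = 1` at realistic counts; the exact interval is slightly conservative at
all counts. `driver_fraction()` converts `w` to the attributable fraction
`(w - 1)/w`, floored at zero.

# Spatial statistics

Contact graphs (`contact_graph_from_coordinates()`) connect residues with
any atom pair within 5 angstrom. The 3D hotspot statistic operationalizes
"a group of residues no more than 5 angstrom apart" as the *neighborhood
ball*: each residue plus its direct contacts, tested for aggregate excess by
a one-sided binomial test against the aggregate expected mass,
BH-corrected within each structure model. Residues covered by significant
neighborhoods merge into connected clusters; clusters sharing residues
across models merge into one reported hotspot, flagged high-confidence only
when every model contributed (the two-tier any-model/all-model convention).
With edgeless graphs this reduces exactly to the single-residue caller,
which is also how the degenerate case is tested. Whether gating uses
q-values (default) or raw p-values is a configuration choice; the raw-p
variant mirrors reporting conventions that quote per-model p < 0.005.

The dimer-interface coldspot test is a two-sided exact binomial test of the
count inside the consensus interface (residues whose cross-chain contact
reproduces in at least 4 of 6 chain pairs) against its mutability-weighted
expectation. The reported fold is the mutability-normalized rate ratio of
outside versus inside, `((n - x)/(1 - p)) / (x/p)`: "mutations occur k
times less often there than elsewhere". The naive expected/observed
quotient is biased low whenever depletion redistributes mass to the rest of
the protein (about 3.6 for a true 3.8 with a 30-residue interface), which
is why the rate-ratio form is used. Conservation contrasts between hotspot
and non-hotspot residues use the two-sample rank-sum test on per-residue
scores (lower = more constrained).

# Cohort handling and MSI imputation

Composite subtype labels follow fixed thresholds: TMB > 100 mutations/Mb is
`MSS-htmb` (POLE-like) and overrides everything; otherwise a known MS status
wins by default (configurable — the treatment of known-MSS tumors with TMB
in [16, 100] is genuinely underdetermined, so `known_status_wins` exposes
both readings); otherwise TMB in [16, 100] is `MT-H` and below 16 is `MT-L`
(half-open at 16); otherwise MSIsensor >= 3.5 or MANTIS >= 0.4 is `MT-H`.

For panels without TMB, `fit_threshold_tree()` re-implements
conditional-inference-style recursive partitioning: at each node the feature
with the smallest permutation-test association p-value is chosen (10,000
label permutations by default, seedable), the node splits only below
`alpha = 0.001`, and the cutoff comes from an exhaustive scan over candidate
thresholds scored by the 2x2 chi-square, with ties resolved to the midpoint
of the widest separating gap — a deterministic rule that also guarantees the
recovered cutoff lies strictly between the straddling order statistics.

Association statistics are intentionally classical: two-sided Fisher exact
tests (probability-summation convention) for co-occurrence, with the
Haldane–Anscombe-corrected sample odds ratio and a Wald interval (the
p-value always comes from the uncorrected exact test); Wilson intervals for
stratified frequencies; Kolmogorov–Smirnov for allele-fraction profiles,
exact when both groups have at most 25 observations. Allele fractions are
normalized per sample to the same tumor's maximum-AF driver mutation — a
per-sample ratio rather than a cohort-level distribution shift, because the
ratio is the quantity on which purity and local copy number cancel to first
order. The global significance convention is 0.005 throughout.

# The synthetic cohort generator

Every estimator above is validated against `simulate_cohort()`, whose
defaults are the study conditions of the motivating cohort: subtype mixture
94.6% MT-L / 4.7% MT-H / 0.7% MSS-htmb; log-normal TMB with medians ~5, ~35
and ~140 mutations/Mb (chosen so each subtype's bulk sits inside its
defining window, with realistic tail overlap); target-gene mutation
probabilities 3.9% / 18.1% / 44% by subtype; an SBS1-like CpG-weighted
spectrum, deletion-skewed homopolymer indels in MT-H and insertion-skewed in
MT-L; driver marginals typical of colorectal tumors (APC 0.70, TP53 0.60,
KRAS 0.45, BRAF 0.10, PIK3CA 0.15, SMAD4 0.10) with pairwise dependence
expressed as log odds ratios and realized by iterative proportional fitting
on the genotype table; and a clonal/subclonal Beta mixture for allele
fractions (means ~0.35 and ~0.10, 25% subclonal).

Selection is implemented by acceptance-resampling: per-substitution weights
(class omega, optionally restricted to LoF-classified changes, divided by
the depletion factor inside the interface) are applied to the mutability
profile and renormalized, so the realized event count is exact and test
tolerances stay simple. Truth labels (class, damage status, clonality,
implanted parameters) are serialized with the cohort, and the same
`(config, seed)` pair regenerates it bit-identically.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: nucleosome positioning, replication timing
and other mesoscale mutability covariates; panel-specific capture footprints
and calling artifacts; cross-study duplicate patients; copy-number structure
beyond a boolean homozygous-deletion flag; and any coupling between
selection and tumor stage or survival. The synthetic gene, score table,
structures and interface are likewise synthetic stand-ins with the right
statistical shape, not reconstructions of any real gene.

# Problem sizes and numerical choices

The validation suite runs at deliberately moderate sizes — 2,000 mutation
events per dN/dS recovery replicate (50 replicates per implanted omega in
{1, 2, 5, 10}), 3,500 events for the 3.8-fold interface depletion recovery,
cohorts of 2,000–5,000 tumors for co-occurrence coverage, and 100 seeds for
each null-calibration check — sizes at which every recovery criterion has
comfortable statistical margin. Monte-Carlo tests use 999 replicates in
tests and 9,999 by default. Degenerate inputs are first-class: single-class
tree fits return a majority leaf, degenerate 2x2 margins are flagged
untestable rather than erroring, zero observed interface counts report an
infinite fold with an exact p-value, and empty mutation sets error early
with plain messages.

# Known limitations

The 3D hotspot statistic tests fixed neighborhood balls; clusters spanning
more than one contact radius are found only through overlap merging, and no
attempt is made to calibrate cluster-level inference beyond the per-residue
BH gate. The dN/dS form is the direct benchmark calculation — no covariate
regression of the dNdScv kind — so residual mutability covariates land in
the selection estimate. Score-based LoF calls inherit whatever biases the
supplied score tables carry, and the shipped cutoffs are calibrated only to
the synthetic score scale. Survival analysis, signature refitting, structure
prediction and clinical-database curation are intentionally out of scope.
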