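Package: somselect
Title: Signature-Aware Selection Analysis of Somatic Mutations in Cancer Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of somatic mutation patterns in a cancer gene against a
    trinucleotide-signature background model. Builds per-site and per-codon
    mutation probability profiles from a 96-channel substitution spectrum,
    ranks predicted against observed hotspots, corrects predictions with
    per-substitution functional scores (lipid phosphatase activity, protein
    abundance, clinical annotations), estimates dN/dS for truncating and
    non-truncating mutation classes, detects single-residue and 3D hotspots on
    residue contact graphs with multi-model consensus, tests dimer-interface
    coldspot depletion, imputes microsatellite status from tumor mutational
    burden and panel features via permutation-based recursive partitioning,
    and computes co-occurrence, allele-fraction and stage-stratified
    statistics. A synthetic-cohort generator with serialized ground truth
    makes every estimator testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
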