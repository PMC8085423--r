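Package: triogxe
Title: Gene-Environment Interaction Analysis for Case-Parent Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-wide gene-environment (GxE) interaction analysis for
    case-parent trio studies using the genotypic transmission disequilibrium
    test (gTDT). Constructs pseudo-controls from untransmitted parental
    alleles, fits the conditional logistic model with gene and gene-by-exposure
    terms via exposure-stratified closed forms, and provides 1 df Wald tests of
    interaction and 2 df joint tests of gene and interaction effects. Includes
    per-SNP quality control (parental minor allele frequency, missingness,
    Mendelian error rate, exact Hardy-Weinberg test among founders, imputation
    quality), scalar and joint two-parameter fixed-effect inverse-variance
    meta-analysis across studies with allele harmonization, genomic-control
    diagnostics, and a simulator of ascertained multi-population trio studies
    for calibration and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
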