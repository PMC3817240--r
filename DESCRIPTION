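Package: pathsel
Title: Pathway Association, Haplotype-Based Selection Scans and eQTL
    Evidence Integration for Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated evidence chain for candidate-pathway studies of
    complex disease: per-SNP case-control logistic association with covariate
    adjustment, gene- and pathway-level adaptive rank truncated product (ARTP)
    permutation tests, extended haplotype homozygosity (EHH) and integrated
    haplotype score (iHS) scans for recent positive selection with a gene-window
    empirical caller, permutation-based cis/trans eQTL mapping, and a final
    multi-evidence intersection report. Ships a haplotype/phenotype/expression
    simulator with known ground truth (mosaic LD panels, imposed selective
    sweeps, logistic disease model, additive cis effects) so every stage is
    testable end to end without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
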