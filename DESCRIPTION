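Package: conada
Title: Conditioning Adaptive Combination of P-Values for Rare-Variant
    Trio Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Region-based rare-variant association testing for
    case-parent trios, with or without unrelated population controls.
    Implements the conditioning adaptive combination of P-values test
    (conADA): per-variant transmission statistics conditional on
    parental genotypes, truncated weighted Fisher combination over a
    grid of P-value truncation thresholds, min-P permutation adjustment
    by trio-level transmission flipping, and sequential Monte Carlo
    early stopping. Includes minor-allele-frequency (Beta density) and
    population-control (Cochran-Armitage trend) weighting schemes, VCF
    and pedigree input, and a synthetic stratified-study simulator for
    type-I-error and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
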