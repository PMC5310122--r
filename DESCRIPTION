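Package: bsaqtl
Title: Bulk Segregant Analysis Simulation and Allele-Frequency-Change QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward simulation of advanced intercross line (AIL) populations
    in yeast, batch serial-dilution selection experiments, and pooled
    sequencing of segregant pools, together with the threshold-based
    allele-frequency-change QTL caller used in bulk segregant analysis and
    the accompanying phenotype statistics: reparameterized Gompertz
    growth-curve fitting by damped Gauss-Newton, broad-sense heritability,
    transgressive segregation, generation counting, fermentation endpoint
    (T100) detection, and replicate comparisons against a control strain
    with Bonferroni correction. Includes an evaluation layer that scores
    called QTL intervals against planted truth (power and false discovery
    rate) and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
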