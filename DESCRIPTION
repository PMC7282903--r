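Package: allelecap
Title: Allele Capture Accounting and Optimization for Ex Situ Conservation Collections
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how much wild (in situ) genetic diversity is held in
    ex situ living collections from diploid multilocus genotype data
    (microsatellites), and how much could be held under random sampling.
    Provides allele tabulation and frequency-category accounting, Monte Carlo
    resampling of wild datasets to estimate allele-capture curves and minimum
    sufficient collection sizes, the genetic conservation gap statistics,
    pairwise Weir-Cockerham FST and allele-frequency-spectrum predictors, and a
    Balding-Nichols synthetic data generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
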