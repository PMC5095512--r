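Package: unseenest
Title: Estimating the Frequency Distribution of Unobserved Genetic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Linear-programming recovery of the population frequency
    distribution of genetic variants, including variants never observed in
    the sequenced cohort, from an observed site-frequency spectrum.
    Provides discovery-curve extrapolation to larger cohorts, a third-order
    jackknife comparator, gene-level loss-of-function frequency estimation,
    census-weighted cohort resampling with hypergeometric allele
    downsampling, a partition-based validation protocol, parsing of
    annotated sites-level VCF (per-population AC/AN, VEP-style CSQ
    consequences with LOFTEE confidence flags), and a synthetic-data
    generator so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    boot,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
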