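Package: selinf
Title: Bayesian Inference for Quantitative Traits Under Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Inference and prediction of quantitative-genetic quantities
    (population means, variance components, pedigree and genomic breeding
    values) when the data arise from a selection process. Selection is encoded
    as a fitness/missingness function that multiplies the likelihood; the
    package provides grid posteriors for scalar parameters under truncation
    and stabilizing (nor-optimal) selection, pedigree and genomic BLUP as
    Gaussian posteriors, selection-corrected Metropolis samplers for
    pre-selected and sequentially culled samples, numeric ignorability
    diagnostics, and seeded synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
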