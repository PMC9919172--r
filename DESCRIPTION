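Package: oakdiff
Title: Diagnostic Marker Discovery and Bayesian Species Assignment for
    European White Oaks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for differentiating Quercus robur and Q. petraea from
    pooled-sequencing variant evidence and a small nuclear marker panel.
    Implements the fixed-difference filter cascade that reduces Pool-seq
    variant tables to species-diagnostic candidates, in-silico genotyping
    of a six-marker panel (CAPS restriction assays, InDel amplicon sizing,
    Sanger base reading) including coding-effect translation, and Bayesian
    multilocus assignment of individuals to Q. robur, Q. petraea or a
    hybrid group with Monte-Carlo exclusion probabilities. A seeded
    synthetic-data generator produces marker-region templates, pool
    variant tables with planted truth and reference genotype panels so
    the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
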