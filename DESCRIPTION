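Package: lopsided
Title: Sample-Size Artifacts in Population Rare-Variant Tallies
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing and demonstrating the sample-size artifact
    in per-population rare-variant discovery: when populations are sampled at
    very different depths, the number of rare variants observed in each
    population tracks its sample size even if every population draws from an
    identical variant pool. The package provides a per-population allele
    count/number (AC/AN) table container with validation, shortlisted-variant
    tallies with origin-rooted (through-origin) regression and its uncentered
    coefficient of determination, a binomial absence-confidence sample-size
    calculator, a carrier-free probability estimator for mixed-karyotype
    (XX/XY) populations covering X-linked and autosomal genes, a binomial
    discovery simulator with analytic expected tallies, TSV and gnomAD-style
    VCF readers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
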