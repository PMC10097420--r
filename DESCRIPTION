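Package: poebias
Title: Meta-Analysis of Parent-of-Origin Allelic Expression Bias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysing parent-of-origin allelic expression
    candidates from reciprocal hybrid mouse crosses. Computes percent allelic
    bias from allele-specific read counts or fold changes, decomposes it into
    parental-origin and strain components, bins genes by maximum bias,
    classifies candidates by genomic context relative to known imprinted
    clusters and imprinting control regions, quantifies cross-study overlap of
    candidate sets, summarises interval signal tracks over strand-aware
    promoter windows, and calls validation status from allele-specific
    pyrosequencing measurements with genomic-DNA amplification-bias
    correction. A synthetic-data generator emulates reciprocal-cross binomial
    allele counts with additive parental and strain effects and noisy
    pyrosequencing assays so that every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
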