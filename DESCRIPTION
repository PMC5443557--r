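Package: scoremeta
Title: Gene Score-Based Meta-Analysis of Two-Phenotype Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates heterogeneous two-phenotype expression studies
    (multiple platforms, human and mouse) into a single ranked gene
    signature using per-study gene scores built from robust median-based
    fold changes, a median-absolute-deviation reproducibility penalty and
    empirical-Bayes significance gating.  Cross-study integration sums
    standardized per-study scores, applies sign-consistency and
    top-percentile filters, and quantifies the evenness of study
    contributions with a Bhattacharyya-distance ratio.  Companion tools
    test chromosome arm and band enrichment of a signature by exact
    binomial tail probabilities and screen downregulated signature genes
    for promoter hypermethylation.  A synthetic-data generator emulates
    multi-study, multi-species inputs with planted effects so the whole
    pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
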