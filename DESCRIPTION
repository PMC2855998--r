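Package: bmadex
Title: Bayesian Model-Averaged Differential Expression with Stability
    Selection and Cluster Permutation Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A case/control expression-profiling pipeline for small-sample
    microarray studies. Scores probe sets for differential expression by
    Bayesian model averaging over lognormal and gamma intensity models
    (posterior probability that the fold change exceeds one), stabilises the
    gene list by leave-one-out cross-validation with Benjamini-Hochberg false
    discovery rate control and an 80 percent selection-frequency rule, tests
    hierarchical cluster concordance of a third high-risk group by Monte
    Carlo label permutation, and validates selected genes with
    delta-delta-Ct qPCR summaries. Ships a synthetic-data generator with
    planted fold changes so the whole chain is testable without any array
    download, plus transcriptions of the study's printed cohort and
    signature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
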