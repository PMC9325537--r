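Package: grnorm
Title: Genomic Reaction Norms from Common-Garden Gene Expression Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes per-gene expression variation from common-garden-gradient
    experiments into genotype, environment, genotype-by-environment and batch
    components; constructs per-genotype reaction norms (intercept and slope of
    log2 expression along an environmental gradient); computes directions and
    magnitudes of differential expression (DE) and differential plasticity (DP)
    under an explicit model-intercept convention; classifies every gene into one
    of twelve canonical expression-pattern categories and, where a genotype is
    designated as an ancestral proxy, into evolutionary sub-patterns (genetic
    compensation, genetic assimilation, reversal). Includes a negative-binomial
    simulator of factorial common-garden designs with known per-gene
    reaction-norm truth, median-of-ratios log2-CPM normalization, per-gene
    variance partitioning, co-expression module summaries, expression-fitness
    permutation tests, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
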