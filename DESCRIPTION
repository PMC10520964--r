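Package: tardistress
Title: Life-History Fitness and Heat-Stress Expression Analysis for
    Tardigrade Temperature Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing temperature-gradient experiments on
    individually reared tardigrades. Derives life-history traits (fecundity,
    fertility, oviposition timing, egg hatching) from per-female clutch
    records, computes a composite fitness score from four min-max normalized
    traits with a zero rule for females that never reproduce, and compares
    traits and fitness across generations and rearing temperatures with
    generalized linear models and the Kruskal-Wallis test. For expression
    data, implements a post-quantification chain: counts-per-million
    transforms, collapsing assembled contigs to genes by shared best BLAST
    hit, empirical control gene selection, removal of unwanted variation via
    factor analysis on control genes, PCA-based outlier sample detection,
    negative-binomial differential expression against the control
    temperature, classification of temperature-response direction, and
    hypergeometric term enrichment with an observed/expected threshold.
    Includes synthetic-data generators with planted ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
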