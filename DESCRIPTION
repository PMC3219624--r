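Package: poolfit
Title: Pooled Tagged Transposon Mutant Fitness Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of pooled, DNA-tagged transposon mutant fitness
    assays of the kind used to build genome-wide gene-phenotype maps in
    bacteria. Converts tag-array intensities into normalized per-strain
    and per-gene log2 fitness values, calibrates a moderated t-like
    statistic against control experiments to obtain empirical-null Z
    scores, classifies genes by phenotype via chi-squared combination
    across conditions, and supports downstream annotation analyses:
    cofitness, per-experiment quality control, operon polarity checks,
    auxotroph concordance, and random-forest prediction of functional
    subroles with operon-aware cross-validation. Includes a synthetic
    data generator with known ground truth so the full pipeline can be
    validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Genetics, Microbiome, FunctionalPrediction, QualityControl
RoxygenNote: 7.3.3
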