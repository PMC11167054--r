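Package: eRNAthermo
Title: Thermodynamic Sequence-to-Expression Modeling of Transcribed Enhancers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study why only a subset of estrogen-receptor-bound
    enhancers are transcribed into enhancer RNA (eRNA). The package labels
    enhancer classes from replicate nascent-transcription peak calls, builds
    motif affinity and pairwise site-adjacency features by PWM scanning with
    p-value calibrated site thresholds, discriminates transcribed from silent
    enhancers with a down-sampled Random Forest, fits ensembles of
    thermodynamics-based sequence-to-expression models under a logistic
    classification objective, derives TF-enhancer regulatory networks by in
    silico knock-downs, and scores non-coding variants by their predicted
    mechanistic impact on enhancer activity. A synthetic-data generator with
    planted regulatory architecture makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    igraph,
    VariantAnnotation,
    SummarizedExperiment,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GeneRegulation, Transcription, MotifAnnotation, Classification,
    NetworkInference, FunctionalPrediction
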