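Package: ampliDepth
Title: Minimum Sequencing Depth Benchmarking for Random-Forest
    Classification of Amplicon Community Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to find the minimum per-sample amplicon sequencing
    depth at which a random-forest classifier of ASV community tables
    retains the predictive performance of the full-depth data.
    Implements exact without-replacement rarefaction ladders,
    out-of-bag evaluation of an mtry/repeat model grid scored by
    Cohen's kappa agreement bands, Chao1-based sampling-coverage
    diagnostics, and class-separability diagnostics (class-frequency
    Gini coefficient, per-feature coefficient of variation across
    class means, shared-feature fractions, and NMDS ordination with
    confidence-ellipse overlap). A Dirichlet-multinomial community
    simulator with controllable class-boundary hardness makes the
    whole procedure testable without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    biomformat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
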