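Package: surprisal
Title: Surprisal Analysis of Gene Expression Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-entropy (surprisal) decomposition of bulk gene-expression
    time or stage series. Log expression is factorized by singular value
    decomposition into a dominant steady-state pattern and condition-dependent
    deviation patterns, each described by per-gene participation weights and
    per-condition Lagrange multipliers. The package reads expression matrices
    in a simple CSV contract, profiles and selects genes per pattern, builds
    symmetric theoretical connectivity heatmaps from products of participation
    weights, compares them with STRING combined-score matrices on identical
    axes, and ships a planted-structure synthetic data generator plus a
    sequential pipeline driver and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'expression-io.R'
    'surprisal-core.R'
    'profiling.R'
    'connectivity.R'
    'heatmap-compare.R'
    'synthetic.R'
    'pipeline.R'
    'plots.R'
    'surprisal-package.R'
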