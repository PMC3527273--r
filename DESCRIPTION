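Package: lineagevar
Title: Lineage-Resolved Statistics of Stress-Induced Phenotypic Variability
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how phenotypic variability arises and propagates
    within bacterial micro-colony lineage trees under sub-inhibitory antibiotic
    stress. Provides a validated lineage-forest data model with a plain-text
    tracking-table dialect and Newick export; sub-lineage and individual
    coefficients of variation (SLCV/IDCV) for differentiation detection;
    within-lineage expression autocorrelation with exponential half-life
    fitting and the linear birth-dilution prediction; sister-progeny
    predisposition tests with resampling nulls, a combinatorial tree
    probability and a direction-bias binomial test; a same-generation lineage
    switch randomization; and a stochastic positive-feedback lineage simulator
    (Euler-Maruyama expression dynamics, growth inhibition, binomial molecule
    partitioning at division, growth-arrest death, optional passive
    co-reporter) that generates realistic tracking data from a single founder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'tree-build.R'
    'tree-accessors.R'
    'tree-io.R'
    'phenotypes.R'
    'variation.R'
    'fate.R'
    'lineagevar-package.R'
    'predisposition.R'
    'memory.R'
    'sim-params.R'
    'simulate.R'
    'moments.R'
    'pipeline.R'
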