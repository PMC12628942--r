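Package: mconet
Title: Multitrophic Co-Occurrence Network Analysis for Soil Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds and analyses multitrophic co-occurrence networks from
    amplicon sequence variant (ASV) count tables of soil bacteria, fungi,
    protists and nematodes. Provides seeded rarefaction, cross-domain table
    merging, prevalence filtering, Pearson and SparCC association inference
    with Benjamini-Hochberg false-discovery-rate control, random-matrix-theory
    (RMT) correlation-threshold selection via nearest-neighbour eigenvalue
    spacing statistics, signed network construction with topology metrics and
    degree-preserving null models, fast-greedy module detection with Zi-Pi
    keystone classification, module eigengene and keystone-guild correlations
    with environmental variables, functional-guild annotation (oligotroph/
    copiotroph, fungal trophic modes, protist feeding groups), and a seeded
    synthetic-community generator with planted modules, connectors and
    environmental couplings for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
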