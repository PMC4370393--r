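Package: dompop
Title: Population Genetics of Dominant Marker Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of dominant (band presence/absence) marker data such as
    ISSR, RAPD and AFLP fingerprints: marker informativeness (PIC, marker
    index, Shannon entropy), within-population diversity under Hardy-Weinberg
    null-allele estimation, AMOVA with permutation testing, pairwise Fst and
    indirect gene flow, Nei's unbiased genetic distance with UPGMA clustering,
    principal coordinates, Mantel isolation-by-distance tests, a Bayesian
    hierarchical model for differentiation (theta) and inbreeding (f) with DIC
    model comparison, admixture-model clustering with Evanno's delta-K, and a
    calibrated simulator of dominant-marker study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'informativeness.R'
    'diversity.R'
    'differentiation.R'
    'distance.R'
    'hickory.R'
    'admixture.R'
    'dompop-package.R'
    'io.R'
    'fixtures.R'
    'pipeline.R'
    'simulate.R'
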