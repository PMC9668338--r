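Package: neodiv
Title: Diversification Trajectories, Pulled Rates, and Bioregionalization for
    Neotropical Clades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits constant, time-dependent, and paleoenvironment-dependent
    birth-death models to time-calibrated phylogenies of extant species with
    incomplete sampling, selects among them by AICc, and classifies each clade
    into one of four diversity-trajectory scenarios (gradual expansion,
    exponential expansion, saturated expansion, waxing-and-waning).
    Cross-checks canonical fits with pulled diversification rates estimated on
    an age grid, derives macroevolutionary bioregions from clade-by-region
    abundance data (Hellinger transform, Morisita-Horn dissimilarity, K-means
    with elbow selection), and compares trajectories across taxa, regions, and
    elevations with exact, rank-based, and phylogenetic tests. Includes forward
    birth-death simulators so the whole pipeline can be exercised on synthetic
    data with known truths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
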