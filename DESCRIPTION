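Package: isotroph
Title: Stable-Isotope Trophic Ecology of Lizard Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for community-level stable isotope analysis of desert
    lizard assemblages: delta notation and two-point standard normalization,
    species-level isotopic summaries and trophic-transfer estimation from
    d15N, weighted trophic rank from stomach-content proportions, habitat
    scores from pitfall-trap measurements with normality-driven transform
    selection, Euclidean distance matrices over ecological spaces, Mantel
    and partial Mantel tests with optional phylogenetically restricted
    permutations, maximum-likelihood estimation of Pagel's lambda, and a
    synthetic-community generator for end-to-end validation of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phytools,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
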