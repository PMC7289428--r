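Package: hexflora
Title: Bee Colour Vision Modelling and Nectar Reward Analysis for Floral Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts floral reflectance spectra into loci in the hexagon
    colour space of hymenopteran trichromatic vision (photon capture under
    von Kries adaptation, receptor excitation, hue angle, chromatic
    contrast, and the six standard colour categories), and tests whether
    nectar sugar reward is associated with bee-perceived colour: median
    dichotomisation, Monte-Carlo chi-square contingency tests over nested
    species subsets, Kendall rank correlation between sugar content and
    chromatic contrast, and phylogenetic signal in sugar content via
    maximum-likelihood estimation of Pagel's lambda on a dated phylogeny.
    Includes a synthetic-data generator (reflectance archetypes, species
    communities, pure-birth trees with lambda-transformed Brownian traits)
    so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    optparse
Config/testthat/edition: 3
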