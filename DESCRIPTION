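Package: fibredough
Title: Physico-Chemical Descriptors of Soluble-Fibre Wheat Doughs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how soluble dietary fibres modulate wheat-dough
    rheology and gluten structure through their plasticizing and humectant
    properties. Computes hydrogen-bond-density descriptors of solvent phases
    (effective water volume fraction, effective Flory-Huggins interaction
    parameter, hydrogen-bonding sites per molar volume) from dough recipes,
    fits the water interaction parameter to moisture sorption isotherms with
    Flory-Huggins theory in the rubbery regime, builds Flory melting-point
    state diagrams for starch gelatinization, extracts features from DSC, DMTA
    and micro-extension curves, quantifies binary gluten-network images
    (skeleton junctions, endpoints, branch lengths, gliding-box lacunarity),
    and relates descriptors to dough responses with reduced-variable backward
    multilinear regression. Includes seeded synthetic-data generators with
    known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    png,
    tiff,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
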