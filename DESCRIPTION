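Package: sacrosim
Title: Lattice Monte Carlo Simulation of Sacrificial-Spheroid Tissue Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metropolis Monte Carlo simulation of adhesion-driven cellular
    rearrangement in bioprinted multicellular constructs on a cubic lattice.
    Provides the 26-neighbor adhesion energy model (works of adhesion,
    interfacial tensions), a reproducible swap-dynamics engine with scheduled
    sacrificial-cell elimination, generators for tubular and branched
    spheroid-based construct geometries (including cell-laden hydrogel slabs),
    and voxel morphometry (connected components, endothelial lining coverage,
    interface roughness, lumen detection) for quantifying tissue fusion,
    cell sorting and perfusable-channel formation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
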