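Package: rootmorph
Title: Depth-Averaged Morphodynamics Around Vertical-Root Vegetation Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled two-dimensional depth-averaged flow, mixed grain-size
    sediment transport and bed evolution around patches of emergent vertical
    roots (cypress knees, mangrove pneumatophores and cone roots) modeled as
    arrays of circular obstacles. Provides scenario generators for hexagonal
    root arrays and flood boundary conditions, a finite-volume shallow-water
    solver with an algebraic turbulence closure, Meyer-Peter-Mueller bedload
    with streamline-curvature directional splitting and mixed-grain
    sheltering, suspended-load advection-diffusion with Itakura-Kishi
    entrainment, Exner bed evolution with an active exchange layer, and
    analysis metrics (viable downstream area, percent velocity change,
    bar-peak distance, optimal root density, inter-patch cooperativity).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
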