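Package: cblflux
Title: Concentration Boundary Layer and Material Flux Analysis for Coral
    Microsensor Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for vertical microsensor profiles (pH on the
    total scale and dissolved oxygen) measured above coral surfaces. Averages
    replicate sensor readings, standardizes profiles to independent bulk
    probes, estimates concentration boundary layer (CBL) thickness by
    log-linear extrapolation to the bulk concentration, and computes proton
    and oxygen flux from Fick's first law on the upper linear gradient of
    each profile. Includes a seawater carbonate system solver (pH_T + total
    alkalinity to pCO2, DIC, carbonate speciation and aragonite saturation
    state), diel surface-oscillation and buoyant-weight calcification
    metrics, factorial linear-model comparisons with Bonferroni-adjusted
    pairwise contrasts, and a seeded generator of synthetic diffusion
    profiles with known ground truth for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    car,
    emmeans,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
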