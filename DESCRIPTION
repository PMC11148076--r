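Package: coralCBL
Title: Concentration Boundary Layer Analysis of Coral Microsensor Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing O2 and pH microsensor profiles measured at
    coral surfaces. Detects the bulk-seawater plateau of a profile, fits
    piecewise-linear concentration gradients by exhaustive BIC-selected
    segmentation, classifies simple versus complex (multi-gradient) profiles,
    and derives concentration boundary layer (CBL) traits: thickness by
    linear extrapolation to the bulk concentration, surface concentration
    change, and diffusive flux via Fick's first law. Includes a seawater
    carbonate-system solver (pH/TA to DIC, DIC/TA to full speciation, with
    Mehrbach-refit and Lueker dissociation-constant sets), NBS-to-total pH
    scale conversion, Reynolds-number flow characterisation, a synthetic
    profile and diel seawater generator for ground-truth recovery testing,
    and trait-aggregation statistics (pooled means, flow ratios, light-dark
    variation, flux-pH correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
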