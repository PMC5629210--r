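Package: junctionmech
Title: Junctional Mechanics and RhoA Signaling Analysis for Epithelial Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for quantifying contractile signaling at
    epithelial adherens junctions. Simulates a bistable junctional
    RhoA-ROCK1-NMIIA feedback network with SRGAP1 acting as an orthogonal
    antagonist, including ramp experiments, fixed-point scans and hysteresis
    analysis. Fits post-ablation vertex recoil curves to a Kelvin-Voigt
    viscoelastic element (initial recoil velocity and relaxation rate
    constant), fits normalized FRAP recovery traces to the one-phase
    association model (mobile fraction, half-time), quantifies junctional
    fluorescence from calibrated images via perpendicular line scans
    (Gaussian peak, two-band area under the curve, co-localization at a
    reference peak, junction-to-cytoplasm ratio), and computes
    mean-squared-displacement summaries of nuclear tracks and wound-margin
    displacement. A synthetic-data module generates every input with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    tiff
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
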