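Package: pamech
Title: Biaxial Wall Mechanics and Microstructure of Murine Pulmonary Arteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of passive and active pulmonary-artery
    biomechanics from ex vivo inflation-extension tests, together with the
    microstructural image analysis that accompanies such experiments.
    Implements thin-wall kinematics and mean Cauchy stresses, a
    four-fiber-family hyperelastic stored-energy function with analytic
    stresses and small-on-large linearized stiffness, multi-start nonlinear
    regression of the material parameters against multi-protocol biaxial
    data, diameter-based distensibility and Bramwell-Hill pulse wave
    velocity, vasoactive-response quantification from diameter time series,
    collagen/smooth-muscle-cell orientation statistics (axial von Mises
    concentration) from multiphoton stacks via circle fitting, polar
    unwrapping and structure-tensor analysis, layer-wise nuclear density
    estimation, and stained-section area fractions with the collagen
    complement rule. Ships synthetic-data generators with known ground
    truth for every input modality so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    lhs,
    pracma,
    igraph,
    jsonlite,
    yaml,
    EBImage
Suggests: testthat (>= 3.0.0), withr, tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
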