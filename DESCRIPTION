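Package: vptRheo
Title: Video Particle-Tracking Microrheology of Biomolecular Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Passive video particle-tracking (VPT) microrheology and image
    quantification for biomolecular condensates such as reconstituted
    pericentriolar-material (PCM) scaffolds. Detects and links sub-pixel
    bead positions (Crocker-Grier style), computes ensemble mean squared
    displacement, inverts it to viscoelastic moduli through the generalized
    Stokes-Einstein relation (Mason's local power-law method with a
    second-order log-curvature correction), fits a Maxwell fluid, and
    extracts the zero-shear viscosity and terminal relaxation time. Also
    provides FRAP recovery-curve normalization and one-phase fitting with
    bootstrap confidence intervals, condensate segmentation with size,
    integrated-density and partition-coefficient statistics, persistence
    curves for extrusion and dilution assays, and a Brownian-dynamics
    generator of bead trajectories in Newtonian and Maxwell media with
    closed-form oracles so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
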