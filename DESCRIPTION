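Package: cavimap
Title: Cavitation Monitoring and MRI Quantification of Focused-Ultrasound
    Blood-Brain-Barrier Opening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification chain linking passive cavitation detection (PCD)
    during focused-ultrasound blood-brain-barrier (BBB) opening to MRI-based
    delivery outcomes. Computes per-pulse harmonic, ultraharmonic and
    broadband cavitation levels and summed cavitation doses from PCD pulse
    waveforms; fits T1 maps from variable-flip-angle SPGR volumes and
    converts pre/post-contrast T1 into gadolinium concentration maps;
    quantifies BBB opening volume, delivered gadolinium amount and delivery
    efficiency with contralateral-background subtraction; segments brain
    tissue by T1 ranges; measures stereotactic targeting accuracy (incidence
    and refraction angles, lateral/axial target shift); and provides the
    dose-versus-outcome statistics. Includes seeded synthetic PCD pulse-train
    and 3D MRI brain-phantom generators with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
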