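Package: microdrive
Title: Microdrive Kinematics, Depth Tracking, and Spike Detection for
    Chronic Extracellular Implants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational companion to a 3D-printed chronic
    electrophysiology implant kit for rats. Converts screwdriver turns to
    micron-scale probe displacement through a cascaded planetary gear
    train and a fine-pitch drive screw, keeps an auditable ledger of
    probe-tip depth from implantation through post-surgical
    micro-adjustments (including print-tolerance calibration), and
    implements the accompanying multichannel pre-processing chain
    (artifact masking, local common average referencing, zero-phase
    Butterworth band-pass) with threshold spike detection, clip
    extraction and cross-channel footprints. A seeded synthetic
    recording generator (background noise, decaying spike templates,
    artifacts, line interference, saline-bath gain-test pulse trains)
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
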