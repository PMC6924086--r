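Package: spinetrack
Title: Contactless Spine Biomechanics Measurement Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline software core of a spine biomechanics testing rig:
    seeded synthetic pseudo-speckle targets, marker-disc scenes and
    strain-gauge signals; a marker-disc detection pipeline (Sobel edge
    enhancement, band thresholding, morphological opening, centroid
    search, track assembly); sub-pixel displacement estimation from
    pseudo-speckle image pairs by Fourier fringe analysis; least-squares
    voltage-to-force gauge calibration; and instant-rigidity computation
    for flexion/extension, lateral bending, axial torsion and axial
    compression loading modes, with intact-versus-implanted
    normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
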