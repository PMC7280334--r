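Package: echowss
Title: Wall Shear Stress Estimation from High-Frame-Rate Contrast-Enhanced
    Ultrasound Image Velocimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating blood flow fields and haemodynamic wall
    shear stress (WSS) from time-resolved B-mode-like ultrasound image
    stacks. Implements singular-value-decomposition clutter filtering,
    multipass window-deforming ensemble-correlation ultrasound image
    velocimetry (echoPIV), proper-orthogonal-decomposition denoising of
    vector fields, vessel-wall tracking by image augmentation, narrow-band
    level-set segmentation and directional peak fitting, and wall shear
    rate / stress estimation via rotation of the strain-rate tensor into
    wall-oriented coordinates, with time-averaged WSS and oscillatory
    shear index maps. Includes a synthetic moving-wall pulsatile-flow
    speckle phantom with an analytic Womersley/Poiseuille ground truth for
    in-silico validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    Matrix,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
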