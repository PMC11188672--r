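Package: sonogate
Title: Retrospectively Gated 3D Ultrasound Reconstruction of Muscle Shape
    During Cyclic Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs three-dimensional skeletal muscle shape during cyclic
    dynamic movement from swept two-dimensional ultrasound. Frames acquired while
    the probe sweeps along the limb are retrospectively gated into one-degree
    joint-angle bins split by movement direction, gated slice stacks are lofted
    into voxel volumes at 10%-of-range-of-motion increments, and morphometry
    (volume, length, cross-sectional-area profile, peak-CSA localization) is
    computed and compared against an ellipsoid muscle model. A synthetic
    deforming-muscle phantom and acquisition-session simulator with known ground
    truth make every stage testable without hardware. Includes joint-angle
    kinematics from motion-capture markers, Stradwin-dialect file export, and the
    accompanying statistical battery (Shapiro-Wilk screening, repeated-measures
    ANOVA or Friedman omnibus tests, ANCOVA slope comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tiff,
    RNifti,
    mgcv,
    EBImage,
    emmeans
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
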