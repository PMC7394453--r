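Package: b0synth
Title: Susceptibility Distortion Correction for Diffusion MRI via Deep b0 Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Corrects susceptibility-induced geometric distortion in
    echo-planar diffusion MRI when only a single phase-encoding direction was
    acquired. A 3D U-Net, trained with a dual-branch truth/difference
    objective, synthesizes an undistorted b0 volume with diffusion contrast
    from a T1-weighted image and the distorted b0; the synthetic volume is
    then treated as a zero-readout (infinite phase-encode bandwidth)
    acquisition so that the susceptibility displacement field can be
    estimated and inverted with Jacobian intensity modulation. A
    physics-based phantom and distortion simulator provides fully testable
    training and evaluation cohorts, and mutual-information / mean-squared
    error metrics quantify the correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
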