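Package: voxdosim
Title: Voxel-Based Patient-Specific Dosimetry for Theranostic
    Radionuclide Therapy
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Patient-specific three-dimensional internal dosimetry for
    targeted radionuclide therapy imaged with a surrogate radionuclide.
    Converts a time series of registered quantitative SPECT/CT images and
    volume-of-interest masks into voxel- and organ-level absorbed dose
    (cGy per MBq injected) for an yttrium-90 therapy vector: planar-based
    field-of-view calibration, time-activity curve construction with
    mono-exponential tail fitting, time-integrated activity maps with
    indium-111 to yttrium-90 decay substitution, a continuous-slowing-down
    beta-particle transport engine with a closed-form local-deposition
    reference mode, and automated lesion uptake grading against mediastinal
    and hepatic reference uptake. Includes a synthetic phantom study
    generator with closed-form ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
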