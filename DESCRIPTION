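Package: birdreg
Title: Bi-Channel Mutual-Information Registration of Whole-Brain Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Atlas registration pipeline for whole-brain volumetric microscopy.
    Preprocesses raw coronal stacks with landmark-driven dynamic z-resampling,
    builds an assistant feature channel (phase congruency and grayscale
    reversal), registers sample and atlas template under a weighted two-channel
    mutual-information cost with rigid, affine and B-spline free-form
    transforms, warps atlas annotations onto the sample, and quantifies
    accuracy with landmark distances, Dice overlap and STAPLE-fused ground
    truth. Includes a synthetic deformable phantom generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
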