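Package: cartMorph
Title: Automated Knee Cartilage Morphometry and Longitudinal Biomarker
    Qualification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated quantification of femorotibial cartilage
    thickness from segmented 3D knee MRI-like volumes, and qualification of
    longitudinal thickness change as an osteoarthritis progression
    biomarker. Provides a synthetic knee phantom generator with analytic
    ground truth, a compact 2D U-Net segmentation stage, atlas-based
    post-processing of subchondral bone segmentations (iterative closest
    point registration, bone-area reconstruction, cartilage linking,
    automated error correction), femoral region-of-interest definition,
    per-plate thickness and denuded-area morphometry, and group-level
    change statistics (standardized response mean with BCa bootstrap
    confidence intervals, Cohen's D, progressor classification,
    chi-square tests).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, RNifti, jsonlite
Suggests: testthat (>= 3.0.0), boot, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
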