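Package: cancellous
Title: Whole-Bone Cancellous Bone Fabric Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying the directional architecture (fabric) of
    cancellous (trabecular) bone from 3D image stacks. Implements CT
    segmentation protocols based on local (Bernsen) thresholding,
    floating-voxel cleaning, isotropic resampling and median-filter
    background subtraction; tiles cancellous regions with close-packed
    spherical volumes of interest; estimates per-VOI fabric tensors by the
    star volume distribution and mean intercept length methods; references
    mean fabric directions in a femoral anatomical coordinate system with
    equal-angle stereographic output; provides major axis regression with a
    permutation test of the slope, the Breusch-Pagan heteroscedasticity
    test, ICC(2,k) scorer reliability and categorical score aggregation; and
    evaluates closed-form torsional buckling of thin-walled tubes. Includes
    synthetic trabecular phantom generators with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr
Config/testthat/edition: 3
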