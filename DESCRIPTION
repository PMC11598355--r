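Package: brainsexmap
Title: Sex Differences Mapping from 3D Brain MRI with a Convolutional
    Classifier and Gradient Saliency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a compact 3D fully convolutional network (an SFCN-style
    architecture with a single sigmoid output) to classify biological sex from
    skull-stripped T1-weighted brain volumes, derives voxelwise gradient class
    saliency maps, and aggregates them into a composite "sex differences map"
    scored against a labelled parcellation.  Includes a synthetic brain-phantom
    cohort generator with a controllable total-intracranial-volume (TIV) sex
    difference and planted regional effects, minimal preprocessing (rigid
    registration, z-score normalisation, mask-based TIV), stratified cohort
    splitting, subgroup performance reporting, and a post-hoc TIV bias audit
    based on volume tertiles and kernel-density overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
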