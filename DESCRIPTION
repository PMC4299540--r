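Package: tumorloc
Title: Automated Lung Tumor Localization in Megavoltage Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated estimation of lung tumor locations in megavoltage
    cone-beam CT (MV-CBCT) verification images for tumor-based patient
    positioning in stereotactic body radiotherapy. Planning-CT tumor templates
    (optionally enhanced with a 3D Sobel filter or a Hessian-eigenvalue
    blob-structure-enhancement filter) are matched against the MV-CBCT by
    exhaustive normalized cross-correlation inside a search region derived
    from a coarse translation-only rigid registration; the placed gross tumor
    volume is binarized by Otsu thresholding and its centroid reported as the
    tumor location. Includes a digital thorax phantom and MV-CBCT degradation
    simulator, per-axis and Euclidean location-error metrics with t/F-test
    comparisons across template modes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
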