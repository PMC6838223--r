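Package: evarstrain
Title: Image-Based Strain Analysis of Abdominal Aortic Aneurysms After EVAR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A CT-angiography time-series registration and biomechanical strain
    analysis pipeline for the post-operative follow-up of abdominal aortic
    aneurysms treated by endovascular repair (EVAR). The pipeline rigidly aligns
    bone anatomy between two follow-up scans, straightens both volumes along the
    aortic centerline (curved planar reformation), recovers a dense displacement
    field of the aneurysm thrombus with a level-set-motion deformable
    registration, and derives voxel-wise tensile and compressive principal
    strains from the right Cauchy-Green deformation tensor. Orientation
    principal-component features of the strain unit-vector fields feed a linear
    support-vector-machine classifier of long-term patient prognosis. A synthetic
    CTA phantom generator with closed-form ground-truth deformation fields makes
    every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    e1071,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
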