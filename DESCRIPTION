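Package: cuereg
Title: Fiducial-Free Monocular 2D-3D Registration with Surface Cues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markerless camera-pose registration of a preoperative 3D organ model
    to monocular endoscopic video via user-drawn surface cues. A cue drawn on the
    organ in a manually aligned keyframe is lifted onto the mesh to create paired
    2D/3D landmarks; the camera pose is then recovered per frame either by
    gradient-based alignment of a differentiable soft-silhouette rendering of the
    cue against a tracked 2D mask (Adam on translation plus a continuous 6D
    rotation parameterization) or by a perspective-n-point RANSAC baseline on the
    tracked keypoints. Includes a synthetic organ-in-cavity scene simulator with
    ground-truth poses and cue masks, pose-perturbation protocols, a
    learning-rate search harness, target-registration-error evaluation, and
    augmented-reality overlay compositing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    yaml,
    png,
    minpack.lm,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
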