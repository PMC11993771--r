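Package: radioplan
Title: Virtual Osteotomy Planning and Accuracy Measurement for the
    Distal Radius
Version: 0.1.0
Authors@R:
    person("Radioplan", "Developers", email = "radioplan@example.org",
           role = c("aut", "cre"))
Description: Geometry and statistics toolkit for patient-specific corrective
    osteotomy of the distal radius. Provides triangle-mesh primitives with STL
    input/output and plane cutting, rigid registration (closed-form Kabsch and
    trimmed Iterative Closest Point), construction of a landmark-based distal
    radius coordinate system (volar tilt, radial inclination, ulnar variance),
    virtual osteotomy planning against a mirrored healthy reference,
    decomposition of residual correction errors into six clinical parameters,
    average-distance-error quality control of 3D-printed guides, paired
    absolute-error noninferiority analysis, and a parametric synthetic radius
    generator with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
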