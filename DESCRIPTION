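Package: periofem
Title: Finite-Element Analysis of Periodontal Ligament Loading Under
    Attachment Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parametric layered tooth-periodontal ligament-bone models for
    single- and multi-rooted teeth, conforming region-tagged tetrahedral
    meshing, static linear-elastic finite-element solves under ramped
    occlusal loading, contact-pressure extraction on the ligament-bone
    interface, and stepwise attachment-loss sweep simulations with
    failure detection.  Includes an isotropic tissue material library,
    mesh-convergence tooling, STL/PLY/VTU import and export, and
    YAML-driven run configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
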