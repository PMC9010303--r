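Package: nucstack
Title: Nucleosome Stacking, Chromatin Fiber Geometry and Bridging-Contact
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geometric analysis of nucleosome stacking and chromatin fiber
    formation mediated by bridging factors such as CENP-N. Derives
    per-nucleosome reference frames from DNA C1' atoms, aligns trajectory
    ensembles by rigid-body superposition, computes inter-nucleosome step
    parameters (rise, shift, tilt, twist), maps protein-DNA contacts to
    superhelical locations (SHL), classifies bridging interfaces,
    parameterizes two-start fiber helices, and quantifies sucrose-gradient
    fractionation profiles. Includes a synthetic pseudo-atomic structure
    generator with known ground truth so that every analysis is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
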