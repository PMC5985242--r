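Package: erproot
Title: Expected Root Position Analysis for Digital Orthodontic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts orthodontic root positions without progress radiographs
    by rigidly registering pre-treatment CBCT-segmented teeth (crown plus
    root) onto later crown-only surface scans using crown geometry alone
    (the expected root position, ERP, method). Provides three-point landmark
    (Kabsch) and iterative-closest-point registration on triangle meshes,
    indirect superimposition of dentitions through a common laser-scan
    frame, plane-based crown/root separation at the cemento-enamel junction,
    signed surface-to-surface displacement fields with three-colour
    deviation maps and summary statistics, PLY/STL input and output, and a
    parametric synthetic dentition generator with ground-truth tooth
    movements for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
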