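Package: rapspec
Title: Structural Determinants of Rap Phosphatase Activity Against Spo0F
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structure- and sequence-based analysis of the interaction between
    Rap-family regulators and the sporulation phosphorelay response regulator
    Spo0F. Provides Shrake-Rupley solvent-accessible surface areas and buried
    interface areas, Kabsch superposition and C-alpha RMSD, backbone
    pseudodihedral angles, receiver-domain switch-state classification
    (Thr82/His101), multiple-sequence-alignment conservation mapped onto the
    complex interface, rotamer-based clash scanning of point substitutions, and
    a rule-based predictor of Spo0F-phosphatase activity for Rap proteins.
    Deterministic synthetic-fixture generators with analytically known answers
    make the whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
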