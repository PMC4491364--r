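Package: esfold
Title: Early-Stage Folding Intermediate Structural Alphabet and
    Statistical-Dictionary Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the early-stage (ES) protein-folding intermediate
    model: a seven-letter structural alphabet defined by minimum-distance
    projection of backbone (phi, psi) dihedrals onto an elliptical path in
    Ramachandran space, a statistical-dictionary predictor that maps
    amino-acid sequences to ES code strings via multi-length substring
    matching with one-mismatch fallback, a tetrapeptide contingency-table
    baseline, Q3-style evaluation measures with three-class groupings
    against DSSP, structure and corpus input/output, and a seeded synthetic
    corpus generator for testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
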