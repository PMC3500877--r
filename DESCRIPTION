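Package: grkin
Title: Kinetic Models of Glucocorticoid Receptor Signalling in Leukemia Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action ordinary differential equation models of
    glucocorticoid receptor (GR) signalling in acute lymphoblastic leukemia
    cell lines: six competing network topologies for GR regulation of c-Jun
    and Bim in glucocorticoid-sensitive CEM-C7-14 cells and for GR/Erg
    crosstalk in sensitive and resistant (CEM-C1-15) cells. Provides a
    stiff-safe simulator for normalized fold-change trajectories, two-stage
    bounded least-squares parameter estimation with multi-start
    initialisation, a normalized least-squares residual for scoring fits,
    residual-based ranking of competing topologies, a linear-versus-
    logarithmic trend classifier for discriminating direct from indirect
    transcription-factor targets, a replicate fold-change time-course
    generator with multiplicative lognormal noise, delimited time-course
    input/output, and SBML Level 3 model export and import.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    Matrix,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
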