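Package: pulsekinetics
Title: Kinetics of Starch and Protein Digestion in Hydrothermally Processed Pulses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying in vitro digestion and texture kinetics of
    pulses (chickpea, pea, black bean) and their isolated cotyledon cells.
    Converts colorimetric assay readings (DNS reducing sugars, OPA free
    alpha-amino groups) into digested-starch and digested-protein
    percentages, fits fractional-conversion and lag-phase logistic kinetic
    models by bounded nonlinear least squares with multistart, derives
    initial reaction rates and joint (SSE/F-ratio) confidence regions for
    parameter pairs, models hardness softening towards a residual plateau
    and the cook times that align samples at that plateau, summarises binned
    volumetric particle-size distributions (cotyledon-cell yield, modality),
    and books proximate-composition ratios (starch/protein, starch to
    fiber-rich residue, seed coat to cotyledon). A synthetic-data module
    generates statistically realistic stand-ins for every measured input so
    the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    lhs,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
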