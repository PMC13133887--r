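Package: fractacomp
Title: Fractal Body-Composition Analysis of CT Tissue Masks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Three-dimensional box-counting fractal analysis (fractal
    dimension, lacunarity, multifractal range) of segmented CT tissue
    masks of the lower extremities, height-normalized volumetric
    body-composition indices, and a diagnostic-model workflow for
    metabolic syndrome: univariate screening, collinearity pruning,
    multivariable logistic regression, and ROC / calibration /
    decision-curve / ICC evaluation. Includes synthetic phantom and
    cohort generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
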