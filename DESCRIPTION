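Package: haemoquant
Title: Haemolysis Quantification in Cattle Serum by UV-VIS and RGB Image
    Colorimetry
Version: 0.1.0
Authors@R:
    person("haemoquant", "developers", email = "maintainer@haemoquant.org",
           role = c("aut", "cre"))
Description: Quantifies the degree of haemolysis in bovine serum from either
    direct UV-VIS absorbance at 540 nm or the colour of a digital photograph
    of the sample. Implements univariate least-squares calibration (absorbance
    and the pseudo-absorbance "Redbance" of the red channel), multivariate
    calibration by NIPALS partial least squares and by a 4-7-1 feed-forward
    neural network trained with backpropagation and momentum, stratified
    calibration/validation splitting and animal-wise tenfold nested
    cross-validation, method-comparison statistics (paired t, line-of-equality
    regression, elliptical joint confidence region), and analytical figures of
    merit (CV%, LOD, LOQ, linearity range, mean recovery). A synthetic
    serum-colour generator emulating the graded-haemolysis study design makes
    the whole pipeline testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jpeg,
    jsonlite,
    png,
    stats,
    tools,
    truncnorm,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
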