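Package: exmquant
Title: Quantitative Image Analysis for Expansion Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative validation and multi-round analysis of
    expansion-microscopy experiments: distortion vector fields and RMS
    length-measurement-error curves from keypoint-matched pre/post-expansion
    image pairs, expansion-factor estimation by keypoint, particle-area,
    length-ratio and tissue-size methods, second-order cross-cumulant SOFI
    reconstruction with drift correction and Richardson-Lucy deconvolution,
    similarity and diffeomorphic-demons registration of sequential staining
    rounds, mutual-information-based unmixing of cumulative staining signal,
    and 3D volume-overlap colocalization matrices with group comparison.
    Includes seeded synthetic-data generators with known ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
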