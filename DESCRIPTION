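Package: seroarray
Title: Autoantibody Profiling from Spotted Protein Macroarray Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies scanned protein-macroarray images into per-antigen
    autoantibody intensity profiles and evaluates their diagnostic value.
    The image pipeline corrects slight scan rotations, segments the array
    into subgrids and spot target areas, separates spot foreground from
    background by exact one-dimensional 2-means clustering, extracts dark
    spots with a black top-hat morphological filter, and averages duplicate
    spots into integer 0-255 profiles. Downstream statistics cover quantile
    normalization, a threshold-sweep per-antigen ROC AUC with an
    informativeness rule, and serum-group classification by linear-kernel
    support vector machines under repeated stratified 10-fold
    cross-validation with stratified label-permutation testing. A synthetic
    array simulator with known ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
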