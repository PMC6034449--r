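Package: vegmorph
Title: Attribute-Morphology Segmentation and Classification of Vegetation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified connected-attribute-morphology pipeline for precision
    agriculture imagery. Vegetation is segmented from NDVI images by selecting
    locally stable, fast-growing regions on a max-tree (component tree), each
    region is described by incrementally computed shape attributes (solidity,
    eccentricity, moment-based circularity and non-compactness, grey range),
    and regions are classified into crop and weed with a maximum-margin
    classifier supporting confidence-based rejection. Global-threshold
    baselines (Otsu, RATS) and precision/recall/F1 evaluation with
    interpolated precision-recall curves are included for comparison, together
    with a deterministic synthetic-field generator producing NDVI-like images
    with per-pixel ground truth and per-region crop/weed/mixed labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    png,
    tiff,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
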