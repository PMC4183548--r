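Package: collagenquant
Title: Quantification of Fibrillar Collagen and Extracellular Matrix in
    Histology Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for quantifying fibrillar collagen and extracellular
    matrix in stained prostate histology. Implements 8-bit hue/saturation/
    brightness thresholding and four-bin hue classification of Picrosirius
    red birefringence under polarized light, blue-ECM scoring of Masson's
    trichrome images, maximum-intensity z-projection scoring of second
    harmonic generation stacks, automated region-of-interest construction
    by exclusion of empty and glandular space, and the accompanying
    statistics (group summaries, pooled two-sample t-tests from raw data or
    printed summary statistics, and univariate regressions of collagen
    metrics on clinical covariates). A seeded synthetic-image generator
    with exact painted ground truth drives validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
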