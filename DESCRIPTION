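Package: clearquant
Title: Staining-Quality Quantification for Cleared-Tissue Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of immunohistochemistry staining quality
    in cleared-tissue 3D fluorescence image stacks. Provides percentile
    normalization, rolling-ball background subtraction and thresholding (or
    import of externally produced segmentation masks), per-plane
    signal/noise/area depth profiles, normalized staining-quality scores,
    depth-to-half-maximum estimation, and blinded replicate comparison against
    a baseline protocol with t-tests. Includes a synthetic-stack generator
    (spheres, tubes, filaments under depth-dependent antibody-penetration
    attenuation, including a reaction-diffusion depletion model) so the whole
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    tiff,
    yaml,
    EBImage,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
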