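Package: hensight
Title: Image-Based Cluster and Unrest Behaviour Analysis for Laying Hens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies group behaviour of floor-housed laying hens from
    overhead video frames. Segments frames into bird blobs (crop, Gaussian
    low-pass, Otsu or fixed threshold, 8-connected components), computes a
    per-frame cluster index from blob morphometry and a per-second unrest
    index from the symmetric Hausdorff distance between centroid sets scaled
    to centimetres by camera geometry, classifies the thermal environment via
    the temperature-humidity index (THI), and compares treatments across
    periods of day and thermal-comfort classes with Tukey-lettered tables.
    Includes an agent-based synthetic flock generator with known ground truth
    for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    jsonlite,
    png,
    igraph,
    mgcv,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    multcomp,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
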