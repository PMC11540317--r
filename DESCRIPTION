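Package: ommatidia
Title: Quantitative Scoring of Ommatidial Lattice Disorder in Drosophila Eye Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects individual ommatidia in bright-field or scanning electron
    microscopy images of the Drosophila compound eye and quantifies the
    disorderliness of their hexagonal arrangement. Each detected ommatidium is
    assigned a fan of six vectors to its nearest neighbors; summed excesses of
    vector lengths over the shortest vector and of angular gaps over the
    smallest gap yield distance and angle disorderliness indices (ODI_D,
    ODI_A), their total (ODI), the detected-ommatidium count (Z), and a
    per-image phenotypic score (P). Includes a synthetic compound-eye image
    generator with ground truth for benchmarking, a parallel batch driver with
    CSV export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    EBImage,
    mgcv,
    png,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    withr
Config/testthat/edition: 3
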