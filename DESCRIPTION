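Package: phenopanel
Title: Cell-Line Panel Selection for High-Content Phenotypic Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores cell lines and cell-line panels for high-content
    phenotypic screening with annotated compound libraries. Per-cell
    morphological feature tables are summarized into signed
    Kolmogorov-Smirnov phenotypic profiles against matched DMSO controls;
    each (cell line, mechanism-of-action) pair is then scored for
    phenoactivity (separation of the MOA point cloud from the DMSO cloud,
    via distance-to-centroid distributions) and phenosimilarity (tightness
    of the MOA cloud relative to each compound's nearest neighbors).
    Cell-line sets are ranked by max-aggregated per-MOA scores with
    compound-subsampling robustness estimates, and a synthetic screen
    generator with planted effect and heterogeneity structure supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
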