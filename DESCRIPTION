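Package: toponome
Title: Combinatorial Molecular Phenotype Analysis for Multiplexed
    Immunofluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pixel-level phenotyping of multiplexed (serial)
    immunofluorescence images. Each pixel's binary present/absent pattern
    across an ordered marker panel is a combinatorial molecular phenotype
    (CMP). The package re-implements the full analysis chain: channel
    alignment, photobleach background subtraction, per-channel
    binarization, merging into per-pixel CMP images, frequency-ranked CMP
    catalogs and marker-specific ("lead protein") tables, cross-sample
    conservation statistics, single-cell top-20-CMP marker profiles,
    hierarchical clustering of cell profiles with a 1/3-2/3 cluster
    composition scoring rule, and Cramér's V association between cluster
    membership and experimental factors. A synthetic image generator with
    planted cell phenotypes and group effects makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
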