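Package: difcycle
Title: Cell-Cycle Choreography of the Bacterial Replication Terminus and
    dif-Cassette Excision Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying when and where the replication terminus
    (ter) of a bacterial chromosome segregates relative to cell division.
    Implements the per-generation dif-cassette excision-frequency estimator
    and recA-dependency statistic for X-Gal plating assays, and a single-cell
    time-lapse/snapshot analysis pipeline: bright-field stack shape
    reconstruction, cell segmentation and lineage tracking with pole
    polarity, per-cell normalized long-axis kymographs and population
    consensus images, septation-onset detection from intensity profiles,
    fluorescent-focus detection, and septation-aligned focus-count
    statistics. A stochastic single-cell simulator (lineages, rendered
    movies, plating counts) with full ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tools,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    generics,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    readr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
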