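Package: scritscreen
Title: Multi-Parametric High-Content Screening of Differential
    Mitochondrial Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for differential mitochondrial toxicity
    high-content screens. Per-cell fluorescence features (TMRM, Hoechst,
    TO-PRO-3) are reduced to per-well signed Kolmogorov-Smirnov distances
    against pooled in-plate untreated controls and to gated viability
    fractions, assembled into SCRIT (Specialized-Cell-Response-to-
    Induced-Toxicity) dose-response fingerprints across glucose and
    galactose growth media, and classified into mechanistic groups by
    Pearson-distance hierarchical clustering and multidimensional
    scaling. Includes a synthetic plate simulator with five mechanistic
    response archetypes, an image renderer, and iCys-style nuclear
    segmentation so the full pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
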