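Package: herbqc
Title: Quality Evaluation of Herbal Extracts by Single-Marker
    Quantification and Quantified Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for HPLC-based quality evaluation of herbal extracts.
    Implements quantitative analysis of multi-components by single marker
    (QAMS) with relative correction factors, log-log calibration of detector
    response, chromatographic method-validation statistics (precision,
    repeatability, stability, recovery), the systematic quantified
    fingerprint method (SQFM) with macro-qualitative similarity,
    macro-quantitative similarity and an eight-grade quality classification,
    and hierarchical cluster analysis of batches. Includes a seeded
    synthetic-data generator for peak tables and batch fingerprints so the
    whole pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
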