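Package: sigconn
Title: Omics Signature Construction, Consensus Aggregation and Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Construct transcriptomic and proteomic perturbation signatures
    from two-group expression matrices with empirical-Bayes moderated
    statistics, aggregate replicate-level z-score signatures into moderated
    Z-score (MODZ) consensus signatures with reproducibility quality control,
    and connect query signatures of four kinds (full signatures,
    differential-expression-only signatures, up/down gene lists and bare gene
    lists) to a signature library using connectivity-map metrics: extreme
    Pearson correlation of signed significances, p-value-weighted Pearson
    correlation, point-biserial up/down correlation, and Random Set
    enrichment. Includes perturbagen-level set connectivity, readers and
    writers for GCT/GMT/TSV signature formats, a synthetic-data generator
    with planted ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
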