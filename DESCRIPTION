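Package: rtkscape
Title: Receptor Tyrosine Kinase Interactome and Phosphorylome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for systematic receptor tyrosine
    kinase (RTK) interactome and phosphorylome studies based on affinity
    purification (AP-MS) and proximity labeling (BioID) mass spectrometry.
    Scores bait-prey pairs from replicate spectral counts with a
    two-component Poisson model and Bayesian false discovery rate, applies a
    compound high-confidence-interactor filter with a
    contaminant-frequency exception, maps interactions against merged
    known-interaction databases with a topology-preserving random-network
    null, builds prey-prey co-purification correlation networks with
    complex-coverage calling, performs Fisher exact annotation enrichment
    with Benjamini-Hochberg correction, compares kinase-dead and wild-type
    interactomes, and post-processes in-vitro kinase assay phosphotyrosine
    sites with motif matching and Ward substrate-profile clustering. A
    synthetic-data module generates every input with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    igraph,
    ape,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
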