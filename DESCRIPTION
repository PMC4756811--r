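Package: backbonemeth
Title: Pan-Cancer CpG-Island and Backbone Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide methylation-array analysis centred on two
    summary axes: average CpG-island (CGI) methylation and average methylation
    of the "backbone", the genomic complement of annotated functional regions
    (CGIs, shores, promoters, 5'-gene bodies, exons, DNase hypersensitive
    sites, transcription-factor binding sites, enhancers and repeats).
    Provides interval algebra for building the region taxonomy, probe-level
    quality masking, per-sample averaging and HC/NC x LB/NB classification,
    per-sample differential-CpG calling with transcription-factor binding-site
    enrichment rates, sliding-window methylation tracks with
    lamina-associated-domain contrasts, a clinical and molecular association
    battery with Benjamini-Hochberg correction including a gene-level
    copy-number scan, and a fully deterministic synthetic-cohort generator so
    that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    GenomeInfoDb,
    IRanges,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
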