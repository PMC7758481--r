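Package: editscan
Title: Detection, Filtering and Immunogenicity Scoring of A-to-I RNA
    Editing Neoantigen Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for identifying HLA-presented neoantigen
    candidates that arise from A-to-I RNA editing. Detects candidate A-to-G
    (and T-to-C) mismatch sites from aligned RNA-seq reads by quality-aware
    pileup, applies a cascade of false-positive filters (known variants,
    read-edge artifacts, splice-proximal intronic sites outside Alu repeats,
    homopolymer-adjacent sites, a panel of normals), annotates coding effects
    strand-aware against transcript models, builds mutant/normal 21-mer long
    peptides and 9-11-mer short peptides, filters candidates on predicted
    MHC-I percentile rank and gene expression, and scores per-sample
    immunogenicity (per-candidate p, RENIS, REscore, cytolytic activity).
    Includes a deterministic synthetic-fixture generator so the whole
    pipeline runs and is tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    SummarizedExperiment,
    tibble,
    tidyr,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
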