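Package: florasm
Title: Desk-Scale De Novo Transcriptome Assembly and Digital Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, desk-scale reimplementation of the classic two-condition
    de novo RNA-seq workflow used for non-model plants: stringent read cleaning
    (chastity flag, adaptor contamination, ambiguous bases, low-quality fraction),
    k-mer de Bruijn assembly of contigs along unambiguous paths, paired-end
    scaffolding with N gaps and read-based gap filling, unigene definition and
    cross-sample clustering into a distinct sequence set, RPKM quantification with
    an Audic-Claverie-type digital expression test and Benjamini-Hochberg FDR
    control, homology-hit annotation with database priority and GO-slim mapping,
    and hypergeometric term enrichment with Bonferroni correction. A synthetic
    data generator produces paired-end reads with known truth for every stage, so
    the whole pipeline can be exercised end to end on a desktop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
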