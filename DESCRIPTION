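Package: ssrmarkers
Title: Microsatellite Mining, Primer Design and In Silico PCR for SSR Marker Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide development of simple sequence repeat (SSR) markers from
    draft genome assemblies. Mines perfect microsatellites (unit lengths 1-6) under
    per-unit-length minimum repeat counts, merges nearby repeats into compound loci,
    classifies every repeat by genic context (exon, intron, intergenic), designs
    flanking PCR primer pairs under length, melting-temperature, GC and product-size
    constraints, links known single-nucleotide polymorphisms to the primer-bounded
    flanking regions, validates primer panels by in silico PCR with a percent-mismatch
    budget, and writes a tab-separated marker database together with the standard
    summary tables. Includes a synthetic-genome simulator that plants repeats, gene
    models and SNPs with full ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
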