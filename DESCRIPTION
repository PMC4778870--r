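Package: ptbseq
Title: Junction-Read Isoform Tests, Conserved Pyrimidine-Tract Scanning,
    and Transcript Truncation Analysis for RNA-Seq
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style toolkit for three bespoke RNA-Seq analyses
    around the Drosophila polypyrimidine tract-binding protein (dmPTB,
    hephaestus): differential isoform usage from exon-exon junction
    ('spliced') read counts via an exact binomial test with log-odds
    ranking and MISO-style filters; a phylogenetic scanner that calls
    C/U-rich PTB binding sites conserved across multi-species genomic
    alignments; and quantification of transcript truncation at a
    transposon insertion from the coverage drop-off in mutant versus
    control pileups. Includes gene-set overlap statistics with a
    hypergeometric expected-by-chance baseline, readers and writers for
    GTF, MAF, bedGraph and BED with explicit coordinate conventions, and
    synthetic-data generators that emulate every input so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
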