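Package: isotail
Title: IsomiR Detection and 3' Non-Templated Tailing Analysis for Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying 3' tailing of mature microRNAs from small
    RNA sequencing libraries. Reads are collapsed and assigned to mature
    miRNAs by exact central-motif matching that tolerates 5' and 3' end
    variability, each isomiR is decomposed into its templated body and 3'
    extension against the genomic context downstream of every annotated
    locus, and extensions are classified as templated ("ambiguous") or
    non-templated (NT) tails with mono/di/mixed nucleotide categories.
    Per-condition profiles summarise 3'-end composition, NT-tail percentages
    and nucleotide identity, tail length by identity decompositions,
    abundance-weighted read lengths, and spike-in based misread rates.
    Conditions are compared through isomiR fold-changes, cumulative
    fold-change curves by isomiR class, enzyme-sensitivity consensus sets,
    terminal-nucleotide preference, and miRNA-level regulation calls across
    knockout and rescue designs. A synthetic-data generator with
    enzyme-specific tailing models (adenylating and uridylating terminal
    nucleotidyltransferases), substrate bias, competition, and a per-base
    misread model provides ground-truth libraries so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, SmallRNA, Transcriptomics, Software
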