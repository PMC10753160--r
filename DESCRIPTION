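Package: T2Tqc
Title: Quality Control and Gene-Family Mining for Telomere-to-Telomere
    Plant Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the bespoke computational steps of a
    telomere-to-telomere (T2T) plant genome project: telomere motif
    scanning and terminal patching from ultra-long read alignments,
    multi-evidence centromere prediction from tandem-repeat arrays in
    fixed genomic windows, k-mer-spectrum consensus quality value (QV)
    estimation, and cytochrome P450 gene-family mining (length filtering
    of profile-HMM hits, tandem gene-cluster detection in annotated gene
    order, pairwise protein identity, SRS6 diagnostic-residue
    classification of flavonoid B-ring hydroxylases, and tissue
    expression summaries). Includes a deterministic synthetic-genome
    generator with a machine-readable truth manifest so every detector
    can be exercised end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
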