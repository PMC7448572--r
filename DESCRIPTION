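Package: karyoscan
Title: Assembly Contiguity, Quality Windows, Telomeres, Centromeres and
    Marker Order Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly quality assessment and chromosome-feature
    characterization for large (mammalian-scale) genome assemblies.
    Computes NCBI-convention contiguity statistics (N50/L50, gap counts,
    placed/unplaced decomposition) from FASTA and AGP; classifies fixed
    windows of the genome from read-alignment summaries into coverage and
    pairing quality categories with GC-normalized depth; detects telomeric
    TTAGGG tandem arrays and applies unit-count, length and density
    retention criteria; filters RepeatMasker annotations by divergence and
    consensus-length fraction and merges centromeric satellite evidence
    into candidate centromere calls; and quantifies SNP-chip probe order
    concordance between a manifest and an assembly by Spearman rank
    correlation with a -1 penalty for unmapped markers. A deterministic
    synthetic-genome generator plants telomeres, satellite arrays, gaps,
    coverage anomalies and probe sets with known truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
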