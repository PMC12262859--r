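Package: xenofrag
Title: Dissecting cfDNA and ctDNA Fragmentomics with Xenograft-Model Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for dissecting the fragmentation
    properties of circulating cell-free DNA (cfDNA) and circulating tumor DNA
    (ctDNA) using cell line-derived xenograft (CDX) designs. Provides a
    synthetic two-species fragment generator with configurable size profiles
    (nucleosomal mode, sub-mononucleosomal periodicity, short-fragment
    enrichment), copy-number weighted genomic placement and imperfect
    species-classifier calls; the ctDNA-isolation logic (control-derived
    blacklists, classifier-call merging, mapping-quality and length filters,
    replicate pooling, down-sampling); fragmentomics feature extraction
    (short-to-long ratio, size histograms and periodicity, 6-mer end and
    breakpoint motif spectra, per-arm fragment size distribution vectors);
    1-Mb copy-number log2-ratio matrices with PCA; and marker statistics
    (pairwise-rank AUC, informative-marker counting, balanced label
    permutation nulls, rank-sum and t tests with BH correction, hierarchical
    clustering).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
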