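Package: chromsieve
Title: De-Noising of 1D Genomic Coverage by Read-Level Empirical Null Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Separates signal from technical noise in 1D genomic coverage
    data (ChIP-seq, CUT&RUN, CUT&Tag, ATAC-seq) without input or spike-in
    controls. Each aligned fragment is tested against an empirical null
    distribution built from pseudo-reads of the same length placed uniformly
    at random on the same chromosome; fragments are partitioned into 'pass'
    (signal) and 'fail' (noise) sets at a user-chosen false discovery rate
    via Benjamini-Hochberg adjustment of add-one empirical p-values. Peaks
    are then called on the pass pile-up with a SICER-style island caller
    (fixed-width windows scored against a Poisson background, merged across
    gaps). Includes exact constant-time interval mean/max queries over
    coverage tracks via a prefix-sum index, a labelled synthetic-data
    generator, and peak-set evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ChIPSeq, ATACSeq, PeakDetection, Coverage, Epigenetics
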