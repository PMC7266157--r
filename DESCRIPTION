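Package: asarscan
Title: Detection and Characterization of ASAR lncRNA Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for screening chromosomes for ASAR
    ("ASynchronous replication and Autosomal RNA") lncRNA candidates.
    Calls contiguous transcribed domains (vlincRNAs, >50 kb of contiguous
    non-genic transcription) from RNA-seq coverage, quantifies LINE-1
    repeat composition against an intron-resampling beta-distribution
    null, calls monoallelic expression and assigns the expressed homolog
    from mono-chromosomal hybrid genotypes, scores RNA-FISH and ReTiSH
    cis/trans coordination of random monoallelic loci, and quantifies
    homolog-resolved BrdU replication timing from metaphase images with
    Kruskal-Wallis group comparison. Includes a synthetic-data generator
    that emulates the statistical structure of the study system so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
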