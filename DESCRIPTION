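Package: peakcoloc
Title: Co-Occupancy Analysis of Transcription-Factor ChIP-Seq Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Interval-level analysis of transcription-factor co-occupancy from
    called ChIP-seq peaks. Provides BED-dialect peak-set containers and
    interval algebra (overlap, co-bound merging, nearest-peak distances,
    genome binning), genomic feature annotation against gene models (promoter
    distance bands, first/other introns and exons, distal intergenic), a
    binned-genome one-sided Fisher's exact co-localization test computed from
    the hypergeometric upper tail in log space (with an exact rational
    enumeration for small tables), histone-mark stratification of peak sets,
    enhancer-table joins with interaction-score filtering, and
    differential-expression joins of peak-target genes. A synthetic-data
    generator produces genomes, gene models, co-bound peak sets, histone-mark
    domains, enhancer tables and differential-expression tables with recorded
    ground truth so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
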