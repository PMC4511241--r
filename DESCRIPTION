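Package: circjunct
Title: Back-Splice Junction Detection and Quantification of Circular RNAs
    from Paired-End RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects circular RNA (circRNA) back-splice junctions from
    paired-end RNA-seq reads by anchor-pair alignment: 25-bp read termini are
    placed on the genome, pairs mapping to the same chromosome and strand in
    reversed genomic order within a bounded span are resolved against
    annotated exon boundaries of a single transcript, and calls are filtered
    by mate consistency and junction-read support. Includes read quality
    control and trimming, expression summaries (FPKM, junction reads per
    million, host-normalized circRNA abundance), ERCC spike-in calibration of
    absolute transcript copy numbers, poly(A)- gene detection, maternal and
    zygotic gene classification, and formation-feature analysis of flanking
    introns (lengths, repeat density, reverse-complementary sequence pairs).
    A synthetic-data generator produces genomes, annotations and paired-end
    reads with planted circRNAs, linear transcripts, trans-splicing decoys,
    ERCC spike-ins and QC-failing reads together with a truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
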