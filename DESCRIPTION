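Package: lctscape
Title: Genome-Wide Detection and Characterization of LINE-1 Antisense
    Promoter Chimeric Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects L1 chimeric transcripts (LCTs) driven by the LINE-1
    antisense promoter (L1-ASP) in stranded paired-end RNA-seq data and
    characterizes them end to end. Builds the reference set of recent,
    ASP-competent L1 elements from a RepeatMasker table and a genome;
    identifies chimeric read pairs (an L1-matching mate plus a
    unique-sequence mate) and clusters them into LCT loci; classifies each
    locus by 5' splice status, genic context, walking-PCR TSS region and
    polyadenylation status; maps transcription start sites from long-read
    alignments into L1-internal coordinates; quantifies expression from
    qPCR cycle thresholds, tests group differences (Mann-Whitney with Holm
    correction) and predicts deregulation from read counts via Hedges' g
    with a calibrated cutoff; and computes restriction-enzyme qPCR (qAMP)
    methylation indices, CNV-expression correlations and scale-regions
    chromatin metaprofiles. A fully specified synthetic-data generator
    (toy genome with planted L1 subfamilies, host genes, LCTs, stranded
    short reads, long reads, Ct tables, methylation assays and coverage
    tracks, with a machine-readable truth table) makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
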