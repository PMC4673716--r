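Package: IsoScan
Title: Full-Length Transcript Analysis for Fragmented Polyploid Draft Genomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-molecule full-length cDNA (Iso-Seq
    style) data against a fragmented draft genome of a polyploid species.
    Covers the whole path from raw multi-pass continuous long reads to an
    annotated isoform catalogue: subread splitting and circular-consensus
    calling, full-length non-chimeric (FLNC) read classification, hybrid
    error correction with short reads, splice-aware mapping with
    coverage/identity scoring, partitioning of reads into mapping groups
    (unique, multi-mapping, cross-contig, low-quality, unmapped),
    splice-junction motif validation, annotation improvement (novel loci,
    contig bridges, gene-model merges, ortholog rescue), junction-chain
    isoform collapsing, stage-wise expression calling (RPKM and
    junction-based isoform presence), and targeted gene-family transcript
    search. Ships a synthetic-data generator that emulates a hexaploid-like
    fragmented genome with homoeologous near-duplicate loci and planted
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    data.table,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
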