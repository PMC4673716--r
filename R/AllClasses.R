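#' @title Core S4 containers
#' @name IsoScan-classes
#' @description S4 containers used throughout the pipeline: gene models,
#'   spliced alignments and FLNC read sets.
NULL

## ---------------------------------------------------------------------------
## GeneModelSet
## ---------------------------------------------------------------------------

#' Set of gene models on a draft genome
#'
#' Thin wrapper around an exon-level [GenomicRanges::GRanges] carrying
#' `gene_id`, `transcript_id` and `exon_rank` metadata columns.  Coordinates
#' follow the IRanges convention (1-based, closed) throughout the package;
#' conversion to/from other conventions happens only at format boundaries.
#'
#' @slot exons exon-level `GRanges` with mcols `gene_id`, `transcript_id`,
#'   `exon_rank`.
#' @export
setClass("GeneModelSet", representation(exons = "GRanges"))

setValidity("GeneModelSet", function(object) {
  ex <- object@exons
  need <- c("gene_id", "transcript_id", "exon_rank")
  if (!all(need %in% colnames(mcols(ex))))
    return(sprintf("exons must carry mcols: %s", paste(need, collapse = ", ")))
  if (length(ex) && any(!as.character(strand(ex)) %in% c("+", "-")))
    return("gene model strand must be '+' or '-'")
  if (length(ex)) {
    sp <- split(seq_along(ex), mcols(ex)$transcript_id)
    for (ii in sp) {
      s <- sort(start(ex)[ii])
      e <- end(ex)[ii][order(start(ex)[ii])]
      if (any(e < s)) return("exon end < start")
      if (length(s) > 1L && any(s[-1] <= e[-length(e)]))
        return("exons of one transcript must be non-overlapping")
    }
  }
  TRUE
})

#' Construct a GeneModelSet
#' @param exons exon-level `GRanges` with mcols `gene_id`, `transcript_id`,
#'   `exon_rank`.
#' @return a `GeneModelSet`
#' @export
GeneModelSet <- function(exons = GRanges()) {
  if (is.null(mcols(exons)$gene_id)) mcols(exons)$gene_id <- character(0)
  if (is.null(mcols(exons)$transcript_id))
    mcols(exons)$transcript_id <- character(0)
  if (is.null(mcols(exons)$exon_rank)) mcols(exons)$exon_rank <- integer(0)
  new("GeneModelSet", exons = exons)
}

#' @describeIn GeneModelSet-accessors exon-level GRanges
#' @export
setGeneric("modelExons", function(x) standardGeneric("modelExons"))

#' @rdname GeneModelSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModelSet-accessors
#' @export
setGeneric("geneSpans", function(x) standardGeneric("geneSpans"))

#' Accessors for GeneModelSet
#' @name GeneModelSet-accessors
#' @param x a `GeneModelSet`
#' @return `modelExons`: exon `GRanges`; `geneIds`: character vector;
#'   `geneSpans`: one `GRanges` entry per gene spanning all its exons.
NULL

#' @rdname GeneModelSet-accessors
#' @export
setMethod("modelExons", "GeneModelSet", function(x) x@exons)

#' @rdname GeneModelSet-accessors
#' @export
setMethod("geneIds", "GeneModelSet",
          function(x) unique(mcols(x@exons)$gene_id))

#' @rdname GeneModelSet-accessors
#' @export
setMethod("geneSpans", "GeneModelSet", function(x) {
  ex <- x@exons
  if (!length(ex)) return(GRanges())
  dt <- data.table(gid = mcols(ex)$gene_id,
                   contig = as.character(seqnames(ex)),
                   strand = as.character(strand(ex)),
                   s = start(ex), e = end(ex))
  sp <- dt[, .(contig = contig[1], strand = strand[1],
               s = min(s), e = max(e)), by = gid]
  GRanges(sp$contig, IRanges(sp$s, sp$e), strand = sp$strand,
          gene_id = sp$gid)
})

setMethod("show", "GeneModelSet", function(object) {
  ex <- object@exons
  cat(sprintf("GeneModelSet: %d genes, %d transcripts, %d exons\n",
              length(unique(mcols(ex)$gene_id)),
              length(unique(mcols(ex)$transcript_id)), length(ex)))
})

#' @export
setMethod("length", "GeneModelSet",
          function(x) length(unique(mcols(x@exons)$gene_id)))

## ---------------------------------------------------------------------------
## SplicedAlignments
## ---------------------------------------------------------------------------

#' Blocked (spliced) read-to-genome alignments
#'
#' One row per alignment.  `blocks` is a list column of integer matrices with
#' columns `qstart, qend, tstart, tend` (1-based, closed), colinear on both
#' read and genome.  `coverage` is the aligned fraction of the read in
#' percent; `identity` is `matches / (matches + mismatches + indels)` in
#' percent (indels counted in gap bases); `score = coverage * identity / 100`.
#'
#' @slot table a `data.frame` with columns `read_id, contig, strand,
#'   read_length, matches, mismatches, indels, coverage, identity, score,
#'   blocks`.
#' @export
setClass("SplicedAlignments", representation(table = "data.frame"))

.aln_cols <- c("read_id", "contig", "strand", "read_length", "matches",
               "mismatches", "indels", "coverage", "identity", "score",
               "blocks")

setValidity("SplicedAlignments", function(object) {
  tb <- object@table
  if (!all(.aln_cols %in% names(tb)))
    return(sprintf("missing columns: %s",
                   paste(setdiff(.aln_cols, names(tb)), collapse = ", ")))
  if (nrow(tb)) {
    if (any(tb$coverage <= 0 | tb$coverage > 100 + 1e-9))
      return("coverage out of (0, 100]")
    if (any(tb$identity <= 0 | tb$identity > 100 + 1e-9))
      return("identity out of (0, 100]")
    for (b in tb$blocks) {
      if (!is.matrix(b) || ncol(b) != 4L) return("blocks must be 4-col matrices")
      if (nrow(b) > 1L) {
        if (any(diff(b[, 1]) <= 0) || any(diff(b[, 3]) <= 0))
          return("blocks must be colinear on read and genome")
        if (any(b[-1, 1] <= b[-nrow(b), 2]) || any(b[-1, 3] <= b[-nrow(b), 4]))
          return("blocks must not overlap")
      }
    }
  }
  TRUE
})

#' Construct a SplicedAlignments object
#' @param table data.frame as described in [SplicedAlignments-class]
#' @return a `SplicedAlignments`
#' @export
SplicedAlignments <- function(table = NULL) {
  if (is.null(table) || !nrow(table)) {
    table <- data.frame(read_id = character(0), contig = character(0),
                        strand = character(0), read_length = integer(0),
                        matches = integer(0), mismatches = integer(0),
                        indels = integer(0), coverage = numeric(0),
                        identity = numeric(0), score = numeric(0))
    table$blocks <- list()
  }
  rownames(table) <- NULL
  new("SplicedAlignments", table = table[, .aln_cols])
}

#' @export
setMethod("length", "SplicedAlignments", function(x) nrow(x@table))

#' Alignment table accessor
#' @param x a `SplicedAlignments`
#' @return the underlying `data.frame`
#' @export
setGeneric("alignmentTable", function(x) standardGeneric("alignmentTable"))

#' @rdname alignmentTable
#' @export
setMethod("alignmentTable", "SplicedAlignments", function(x) x@table)

setMethod("show", "SplicedAlignments", function(object) {
  tb <- object@table
  cat(sprintf("SplicedAlignments: %d alignments, %d reads, %d contigs\n",
              nrow(tb), length(unique(tb$read_id)),
              length(unique(tb$contig))))
  if (nrow(tb))
    cat(sprintf("  coverage %.1f-%.1f%%, identity %.1f-%.1f%%\n",
                min(tb$coverage), max(tb$coverage),
                min(tb$identity), max(tb$identity)))
})

#' @export
setMethod("[", "SplicedAlignments", function(x, i, j, ..., drop = FALSE) {
  SplicedAlignments(x@table[i, , drop = FALSE])
})

#' Concatenate SplicedAlignments
#' @param x,... `SplicedAlignments` objects
#' @return a combined `SplicedAlignments`
#' @export
setMethod("c", "SplicedAlignments", function(x, ...) {
  tabs <- lapply(c(list(x), list(...)), alignmentTable)
  SplicedAlignments(do.call(rbind, tabs))
})

## ---------------------------------------------------------------------------
## FlncSet
## ---------------------------------------------------------------------------

#' Set of full-length non-chimeric (FLNC) reads
#'
#' Oriented (sense strand), primer- and poly(A)-trimmed transcript reads
#' together with their derivation metadata.
#'
#' @slot sequences `DNAStringSet` of trimmed sense-strand sequences.
#' @slot info `data.frame` with one row per read: `id`, `polya_len`,
#'   `had_5p_primer`, `had_3p_primer`, `source_type` ("I" for >= 2 subreads,
#'   "II" for a single pass), `n_passes`, `corrected`.
#' @export
setClass("FlncSet",
         representation(sequences = "DNAStringSet", info = "data.frame"))

setValidity("FlncSet", function(object) {
  if (length(object@sequences) != nrow(object@info))
    return("sequences and info must have equal length")
  need <- c("id", "polya_len", "had_5p_primer", "had_3p_primer",
            "source_type", "n_passes", "corrected")
  if (!all(need %in% names(object@info)))
    return(sprintf("info must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(object@info)) {
    if (anyDuplicated(object@info$id)) return("duplicate read ids")
    if (!all(object@info$had_5p_primer) || !all(object@info$had_3p_primer))
      return("FLNC reads must carry both primers")
    if (!all(object@info$source_type %in% c("I", "II")))
      return("source_type must be 'I' or 'II'")
  }
  TRUE
})

#' Construct an FlncSet
#' @param sequences `DNAStringSet` of trimmed, oriented read sequences
#' @param info metadata `data.frame` (see [FlncSet-class])
#' @return an `FlncSet`
#' @export
FlncSet <- function(sequences = DNAStringSet(), info = NULL) {
  if (is.null(info)) {
    info <- data.frame(id = character(0), polya_len = integer(0),
                       had_5p_primer = logical(0), had_3p_primer = logical(0),
                       source_type = character(0), n_passes = integer(0),
                       corrected = logical(0))
  }
  rownames(info) <- NULL
  names(sequences) <- info$id
  new("FlncSet", sequences = sequences, info = info)
}

#' @export
setMethod("length", "FlncSet", function(x) length(x@sequences))

#' FlncSet accessors
#' @param x an `FlncSet`
#' @return `flncSequences`: the `DNAStringSet`; `flncInfo`: metadata
#'   `data.frame`.
#' @name FlncSet-accessors
NULL

#' @rdname FlncSet-accessors
#' @export
setGeneric("flncSequences", function(x) standardGeneric("flncSequences"))

#' @rdname FlncSet-accessors
#' @export
setGeneric("flncInfo", function(x) standardGeneric("flncInfo"))

#' @rdname FlncSet-accessors
#' @export
setMethod("flncSequences", "FlncSet", function(x) x@sequences)

#' @rdname FlncSet-accessors
#' @export
setMethod("flncInfo", "FlncSet", function(x) x@info)

setMethod("show", "FlncSet", function(object) {
  inf <- object@info
  cat(sprintf("FlncSet: %d reads (type I: %d, type II: %d)\n",
              nrow(inf), sum(inf$source_type == "I"),
              sum(inf$source_type == "II")))
  if (nrow(inf))
    cat(sprintf("  length %d-%d nt, mean poly(A) %.1f nt, corrected: %d\n",
                min(Biostrings::nchar(object@sequences)),
                max(Biostrings::nchar(object@sequences)),
                mean(inf$polya_len), sum(inf$corrected)))
})

#' @export
setMethod("[", "FlncSet", function(x, i, j, ..., drop = FALSE) {
  FlncSet(x@sequences[i], x@info[i, , drop = FALSE])
})
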