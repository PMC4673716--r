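## Splice-aware mapping of FLNC reads to a draft genome: k-mer seeding,
## colinear chaining, block refinement with canonical-motif intron placement,
## coverage/identity scoring and best-locus selection.

#' Aligner parameters
#'
#' @param k seed k-mer size
#' @param min_intron smallest genomic gap treated as an intron (smaller gaps
#'   are indels)
#' @param max_intron largest genomic gap bridged by chaining
#' @param max_read_gap largest seed gap on the read bridged by chaining
#' @param min_identity minimum identity (percent) for a reported alignment
#' @param min_coverage minimum read coverage (percent) for a reported
#'   alignment
#' @param tie_delta score difference below which two alignments count as
#'   tied best ("multiple best alignments")
#' @param max_kmer_hits seeds occurring more often than this in the genome
#'   are masked as repeats
#' @return a list of class `AlignParams`
#' @export
alignParams <- function(k = 15L, min_intron = 40L, max_intron = 6000L,
                        max_read_gap = 400L, min_identity = 40,
                        min_coverage = 30, tie_delta = 0.1,
                        max_kmer_hits = 32L) {
  p <- list(k = as.integer(k), min_intron = as.integer(min_intron),
            max_intron = as.integer(max_intron),
            max_read_gap = as.integer(max_read_gap),
            min_identity = min_identity, min_coverage = min_coverage,
            tie_delta = tie_delta, max_kmer_hits = as.integer(max_kmer_hits))
  stopifnot(p$k >= 8L, p$k <= 15L, p$min_intron > 0L,
            p$max_intron > p$min_intron)
  class(p) <- "AlignParams"
  p
}

#' Build a k-mer index of a genome
#'
#' @param genome named `DNAStringSet` of contigs
#' @param params an [alignParams]
#' @return an opaque index object for [toySplicedAlign]
#' @export
genomeIndex <- function(genome, params = alignParams()) {
  stopifnot(!is.null(names(genome)), !anyDuplicated(names(genome)))
  seqs <- as.character(genome)
  kt <- kmer_table_cpp(seqs, params$k, 1L)
  idx <- data.table(kmer = kt$kmer, ci = kt$id, gp = kt$pos)
  # mask repetitive seeds
  cnt <- idx[, .N, by = kmer]
  idx <- idx[!cnt[N > params$max_kmer_hits], on = "kmer"]
  setkey(idx, kmer)
  structure(list(index = idx, contigs = names(genome), seqs = seqs,
                 params = params),
            class = "GenomeIndex")
}

#' Splice-aware alignment of reads against a toy-scale genome
#'
#' Exact k-mer seeds are chained colinearly per contig and orientation;
#' inter-seed gaps are closed by banded alignment; genomic gaps of at least
#' `min_intron` become introns with boundaries shifted (up to 6 nt) to the
#' nearest canonical splice motif (GT..AG, then GC..AG, AT..AC).  All
#' alignments with identity >= `min_identity` and coverage >= `min_coverage`
#' are reported -- at most one (the best) per contig.
#'
#' `strand` records the orientation of the read on the contig ("+" = read as
#' given); the transcriptional strand is derived by [determineStrand].
#'
#' @param reads named `DNAStringSet`
#' @param genome named `DNAStringSet` of contigs, or a prebuilt
#'   [genomeIndex]
#' @param params an [alignParams] (ignored when `genome` is an index)
#' @return a [SplicedAlignments] with all reported alignments, sorted by
#'   read and descending score
#' @export
toySplicedAlign <- function(reads, genome, params = alignParams()) {
  gi <- if (inherits(genome, "GenomeIndex")) genome
        else genomeIndex(genome, params)
  params <- gi$params
  k <- params$k
  rseq_fwd <- as.character(reads)
  rows <- vector("list", 256L); nrow_used <- 0L
  for (ri in seq_along(rseq_fwd)) {
    rl <- nchar(rseq_fwd[ri])
    if (rl < k) next
    for (orient in c("+", "-")) {
      rs <- if (orient == "+") rseq_fwd[ri] else .revcomp_chr(rseq_fwd[ri])
      cod <- kmer_codes_cpp(rs, k)
      ok <- which(cod >= 0L)
      if (!length(ok)) next
      q <- data.table(kmer = cod[ok], rp = ok)
      hits <- gi$index[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (!nrow(hits)) next
      for (cix in unique(hits$ci)) {
        h <- hits[hits[["ci"]] == cix]
        ch <- chain_anchors_cpp(h$rp, h$gp, k, params$max_intron,
                                params$max_read_gap, 64L)
        if (length(ch$idx) < 1L) next
        if (length(ch$idx) * k < 0.5 * params$min_coverage / 100 * rl) next
        sel <- ch$idx[order(h$rp[ch$idx])]
        ref <- refine_chain_cpp(rs, gi$seqs[cix], h$rp[sel], h$gp[sel],
                                k, params$min_intron)
        bl <- ref$blocks
        aligned <- sum(bl[, "qend"] - bl[, "qstart"] + 1L)
        denom <- ref$nmatch + ref$nmismatch + ref$nindel
        if (denom == 0L) next
        cov <- 100 * aligned / rl
        ident <- 100 * ref$nmatch / denom
        if (cov < params$min_coverage || ident < params$min_identity) next
        ## for "-" alignments, read coordinates stay on the aligned
        ## (reverse-complemented) read, PSL-style, so blocks ascend on both
        ## axes; consumers translate via the strand column when needed
        nrow_used <- nrow_used + 1L
        if (nrow_used > length(rows)) rows <- c(rows, vector("list", length(rows)))
        r <- data.frame(read_id = names(reads)[ri], contig = gi$contigs[cix],
                        strand = orient, read_length = rl,
                        matches = ref$nmatch, mismatches = ref$nmismatch,
                        indels = ref$nindel, coverage = cov,
                        identity = ident, score = cov * ident / 100,
                        stringsAsFactors = FALSE)
        r$blocks <- list(bl)
        rows[[nrow_used]] <- r
      }
    }
  }
  if (!nrow_used) return(SplicedAlignments())
  tab <- do.call(rbind, rows[seq_len(nrow_used)])
  ## keep only the better orientation per (read, contig) unless nearly tied
  dt <- as.data.table(tab[, c("read_id", "contig", "strand", "score")])
  dt[, ix := .I]
  keepix <- dt[, .(ix = ix[score >= max(score) - 0.05]),
               by = .(read_id, contig)]$ix
  tab <- tab[sort(keepix), , drop = FALSE]
  tab <- tab[order(tab$read_id, -tab$score), , drop = FALSE]
  SplicedAlignments(tab)
}

#' Coverage and identity of a blocked alignment
#'
#' Coverage is the aligned fraction of the read
#' (`100 * sum(block read lengths) / read_length`); identity is
#' `100 * matches / (matches + mismatches + indels)` with indels counted in
#' gap bases.  Values are kept at full precision internally and rounded only
#' for reporting.
#'
#' @param matches,mismatches,indels alignment counts
#' @param aligned_read_bases total read bases inside blocks
#' @param read_length full read length
#' @return named numeric vector `c(coverage =, identity =)`
#' @export
computeCoverageIdentity <- function(matches, mismatches, indels,
                                    aligned_read_bases, read_length) {
  if (aligned_read_bases <= 0L) stop("zero aligned length")
  if (read_length <= 0L) stop("read_length must be positive")
  c(coverage = 100 * aligned_read_bases / read_length,
    identity = 100 * matches / (matches + mismatches + indels))
}

#' Best-locus selection for one read
#'
#' Maximises `score = coverage * identity / 100`.  When the top two scores
#' differ by less than `tie_delta` the read is ambiguous (multiple best
#' alignments, the substrate of the multi-mapping read group).  Ties are
#' ordered deterministically by (contig, genome start) for reporting.
#'
#' @param alnset a [SplicedAlignments] holding one read's alignments
#' @param tie_delta score tie threshold
#' @return list with `best` (single-row alignment table or `NULL`),
#'   `ambiguous` (logical) and `tied` (table of tied-best alignments)
#' @export
selectBestLocus <- function(alnset, tie_delta = 0.1) {
  tb <- if (is(alnset, "SplicedAlignments")) alignmentTable(alnset) else alnset
  if (!nrow(tb)) stop("empty alignment set")
  stopifnot(length(unique(tb$read_id)) == 1L)
  gstart <- vapply(tb$blocks, function(b) as.numeric(b[1, "tstart"]), 0)
  tb <- tb[order(-tb$score, tb$contig, gstart), , drop = FALSE]
  tied <- tb[tb$score >= tb$score[1] - tie_delta, , drop = FALSE]
  list(best = tb[1, , drop = FALSE],
       ambiguous = nrow(tied) >= 2L,
       tied = tied)
}

#' Transcriptional strand of an aligned read
#'
#' With at least one intron, the strand follows the canonical splice motifs
#' (GT..AG etc. read forward = "+", their reverse complements = "-");
#' conflicting motifs give "?".  Single-exon alignments inherit the
#' alignment orientation of the (already oriented, sense-strand) FLNC read;
#' "?" when the read aligns (nearly) equally well in both orientations.
#'
#' @param aln single-row alignment table (from [alignmentTable])
#' @param genome named `DNAStringSet` (or character) of contigs
#' @param both_orient_scores optional numeric vector of this read's scores
#'   on the same contig in both orientations (for the single-exon tie rule)
#' @param tie_delta score tie threshold
#' @return "+", "-" or "?"
#' @export
determineStrand <- function(aln, genome, both_orient_scores = NULL,
                            tie_delta = 0.1) {
  b <- aln$blocks[[1]]
  if (nrow(b) >= 2L) {
    g <- as.character(genome[[aln$contig]])
    sense <- 0L; anti <- 0L
    for (i in seq_len(nrow(b) - 1L)) {
      donor <- b[i, "tend"] + 1L
      acceptor <- b[i + 1L, "tstart"] - 1L
      if (acceptor - donor + 1L < 4L) next
      mo <- paste0(substr(g, donor, donor + 1L),
                   substr(g, acceptor - 1L, acceptor))
      if (mo %in% c("GTAG", "GCAG", "ATAC")) sense <- sense + 1L
      else if (mo %in% c("CTAC", "CTGC", "GTAT")) anti <- anti + 1L
    }
    if (sense > 0L && anti == 0L) return("+")
    if (anti > 0L && sense == 0L) return("-")
    if (sense == 0L && anti == 0L) {
      # no canonical motif at all: fall back to alignment orientation
      return(aln$strand)
    }
    return("?")
  }
  if (!is.null(both_orient_scores) && length(both_orient_scores) >= 2L) {
    s <- sort(both_orient_scores, decreasing = TRUE)
    if (s[1] - s[2] < tie_delta) return("?")
  }
  aln$strand
}
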