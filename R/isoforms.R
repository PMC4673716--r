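## Collapse high-quality reads into unique transcripts per locus and compute
## catalogue statistics.  Two transcripts of a multi-exon gene are different
## isoforms when they differ in at least one intron/exon junction; junction
## chains are compared exactly (residual wobble is handled upstream by
## shifting intron edges onto canonical motifs).

#' Collapse reads into unique transcript isoforms
#'
#' Reads of one locus are grouped by identical junction chain; all
#' single-exon reads of a locus (same strand by construction) collapse to a
#' single isoform.  The representative read is the longest.  An isoform is
#' KNOWN when its chain exactly matches an annotated transcript's chain at
#' its contig (single-exon: when the locus is EXTANT with a single-exon
#' model), NOVEL_AT_KNOWN_LOCUS when the locus is annotated but the chain is
#' new, NOVEL_LOCUS otherwise.
#'
#' @param hq result of [filterHighQuality]
#' @param loci result of [assignLoci]
#' @param aln draft [SplicedAlignments] (for representative blocks/lengths)
#' @param models draft [GeneModelSet]
#' @param min_intron smallest genomic gap regarded as a junction
#' @return `data.frame` of isoforms with junction chain, span, length,
#'   status, representative read and support; `blocks` holds the
#'   representative read's alignment blocks
#' @export
collapseIsoforms <- function(hq, loci, aln, models, min_intron = 40L) {
  info <- hq$read_info[hq$read_info$read_id %in% hq$kept, , drop = FALSE]
  lmap <- setNames(loci$reads$locus_id, loci$reads$read_id)
  info$locus_id <- unname(lmap[info$read_id])
  best <- .best_per_read(aln)
  rownames(best) <- best$read_id
  ltab <- loci$loci
  rownames(ltab) <- ltab$locus_id
  ## annotated chains per contig for KNOWN status
  mex <- modelExons(models)
  model_chain <- character(0)
  model_single <- character(0)   # contigs::strand spans of 1-exon models
  if (length(mex)) {
    sp <- split(seq_along(mex), mcols(mex)$transcript_id)
    for (ii in sp) {
      ii <- ii[order(start(mex)[ii])]
      ctg <- as.character(seqnames(mex))[ii[1]]
      std <- as.character(strand(mex))[ii[1]]
      if (length(ii) == 1L) {
        model_single <- c(model_single, paste0(ctg, "::", std))
        next
      }
      d <- end(mex)[ii][-length(ii)] + 1L
      a <- start(mex)[ii][-1L] - 1L
      ch <- sprintf("%d-%d", d, a)
      if (std == "-") ch <- rev(ch)
      model_chain <- c(model_chain,
                       paste0(ctg, "|", paste(ch, collapse = ";")))
    }
  }
  out <- list()
  for (lc in unique(info$locus_id)) {
    ii <- which(info$locus_id == lc)
    lstat <- ltab[lc, "status"]
    multi <- ii[lengths(info$chain_list[ii]) >= 1L]
    single <- setdiff(ii, multi)
    groupsl <- split(multi, info$chain[multi])
    if (length(single)) groupsl <- c(groupsl, list(.single = single))
    for (gname in names(groupsl)) {
      gg <- groupsl[[gname]]
      rl <- best[info$read_id[gg], "read_length"]
      rep_i <- gg[which.max(rl)]
      rep_id <- info$read_id[rep_i]
      b <- best[rep_id, "blocks"][[1]]
      chain <- info$chain[rep_i]
      is_single <- gname == ".single"
      status <-
        if (is_single) {
          if (lstat == "EXTANT" &&
              paste0(info$contig[rep_i], "::", info$strand[rep_i]) %in%
                model_single) "KNOWN"
          else if (lstat == "EXTANT") "NOVEL_AT_KNOWN_LOCUS"
          else "NOVEL_LOCUS"
        } else if (paste0(info$contig[rep_i], "|", chain) %in% model_chain) {
          "KNOWN"
        } else if (lstat == "EXTANT") "NOVEL_AT_KNOWN_LOCUS"
        else "NOVEL_LOCUS"
      r <- data.frame(
        transcript_id = sprintf("%s.t%02d", lc, length(out) + 1L),
        locus_id = lc, contig = info$contig[rep_i],
        strand = info$strand[rep_i],
        chain = if (is_single) "" else chain,
        span_start = min(b[, "tstart"]), span_end = max(b[, "tend"]),
        length_bp = sum(b[, "qend"] - b[, "qstart"] + 1L),
        status = status, representative_read = rep_id,
        n_supporting_reads = length(gg),
        coverage = best[rep_id, "coverage"],
        identity = best[rep_id, "identity"],
        stringsAsFactors = FALSE)
      r$blocks <- list(b)
      out[[length(out) + 1L]] <- r
    }
  }
  iso <- do.call(rbind, out)
  iso$transcript_id <- sprintf(
    "%s.t%02d", iso$locus_id,
    stats::ave(seq_len(nrow(iso)), iso$locus_id, FUN = seq_along))
  rownames(iso) <- NULL
  iso
}

#' Length statistics of transcript sets
#'
#' @param novel,known integer vectors of transcript lengths (bp)
#' @return list with per-set min/max/mean (nearest bp) and the difference of
#'   means (novel minus known)
#' @export
transcriptLengthStats <- function(novel, known) {
  if (!length(novel) || !length(known)) stop("empty transcript set")
  st <- function(x) c(min = min(x), max = max(x), mean = round(mean(x)))
  list(novel = st(novel), known = st(known),
       mean_difference = round(mean(novel)) - round(mean(known)))
}

#' Histogram of per-locus read support
#'
#' Deterministic inclusive bins as conventionally printed: 1, 2-10, 11-100,
#' more than 100 reads.
#'
#' @param n_reads integer vector of per-locus read counts
#' @return list with `counts` and `percent`
#' @export
locusSupportHistogram <- function(n_reads) {
  bins <- c(`1` = sum(n_reads == 1L),
            `2-10` = sum(n_reads >= 2L & n_reads <= 10L),
            `11-100` = sum(n_reads >= 11L & n_reads <= 100L),
            `>100` = sum(n_reads > 100L))
  list(counts = bins, percent = round(100 * bins / max(1L, sum(bins)), 1))
}
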