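## Annotation improvement: high-quality read filtering, locus assignment
## (extant vs novel), contig-bridge detection from cross-contig reads,
## spanning-transcript (gene-merge) detection, ortholog rescue of poorly
## mapped reads, and ORF-completeness estimation against reference cDNAs.

# forward-read coordinates of an alignment's blocks (q coords are stored on
# the aligned orientation; flip for "-")
.fwd_q <- function(blocks, strand, read_length) {
  if (strand == "+") return(blocks[, c("qstart", "qend"), drop = FALSE])
  cbind(qstart = read_length - blocks[, "qend"] + 1L,
        qend = read_length - blocks[, "qstart"] + 1L)
}

# junction chain of one alignment in transcription order, as
# "donor-acceptor" strings; tx_strand decides the order
.chain_of <- function(blocks, tx_strand, min_intron = 40L) {
  if (nrow(blocks) < 2L) return(character(0))
  d <- blocks[-nrow(blocks), "tend"] + 1L
  a <- blocks[-1L, "tstart"] - 1L
  keep <- (a - d + 1L) >= min_intron
  ch <- sprintf("%d-%d", d[keep], a[keep])
  if (identical(tx_strand, "-")) rev(ch) else ch
}

# best alignment per read as a plain table with list-column blocks
.best_per_read <- function(aln, tie_delta = 0.1) {
  tb <- alignmentTable(aln)
  sp <- split(seq_len(nrow(tb)), tb$read_id)
  rows <- lapply(sp, function(ii)
    selectBestLocus(tb[ii, , drop = FALSE], tie_delta)$best)
  do.call(rbind, rows)
}

# single-linkage clustering of reads by >= 1 bp exonic overlap on the same
# contig and strand; returns an integer cluster id per row of `spans`
.cluster_by_overlap <- function(exons_gr, read_of_exon) {
  if (!length(exons_gr)) return(integer(0))
  ov <- findOverlaps(exons_gr, exons_gr)
  from <- read_of_exon[S4Vectors::queryHits(ov)]
  to <- read_of_exon[S4Vectors::subjectHits(ov)]
  g <- graph_from_data_frame(
    data.frame(from = from, to = to), directed = FALSE,
    vertices = unique(read_of_exon))
  comp <- components(g)$membership
  comp[unique(read_of_exon)]
}

#' High-quality filtering of uniquely mapped reads
#'
#' Removes (1) reads missing 5' exons: a read whose junction chain is a
#' strict suffix of another same-locus read's chain with its 5' end
#' downstream of that read's; and (2) unsupported singletons: the only read
#' of its junction chain at its locus with no short-read support on any of
#' its junctions (single-exon singletons: no overlapping short-read
#' coverage).
#'
#' @param groups result of [classifyReadGroups] (G1 reads are filtered)
#' @param aln a [SplicedAlignments]
#' @param junction_support `data.frame` with `contig, donor, acceptor,
#'   support_count` (e.g. from [shortReadEvidence])
#' @param short_reads pooled `DNAStringSet` of short reads (coverage check
#'   for single-exon singletons); `NULL` skips that check
#' @param genome named `DNAStringSet` (needed with `short_reads`)
#' @param min_intron smallest genomic gap regarded as a junction
#' @return list with `kept`, `removed_5prime_truncated`,
#'   `removed_unsupported_singletons` (read-id vectors) and `read_info`
#'   (per-read table: locus cluster, chain, strand, span)
#' @export
filterHighQuality <- function(groups, aln, junction_support,
                              short_reads = NULL, genome = NULL,
                              min_intron = 40L) {
  g1 <- groups[groups$group == "G1", , drop = FALSE]
  best <- .best_per_read(aln)
  best <- best[best$read_id %in% g1$read_id, , drop = FALSE]
  strand_of <- setNames(g1$strand, g1$read_id)
  info <- data.frame(read_id = best$read_id, contig = best$contig,
                     strand = unname(strand_of[best$read_id]),
                     stringsAsFactors = FALSE)
  info$chain_list <- lapply(seq_len(nrow(best)), function(i)
    .chain_of(best$blocks[[i]], info$strand[i], min_intron))
  info$chain <- vapply(info$chain_list, paste, "", collapse = ";")
  info$span_start <- vapply(best$blocks, function(b) min(b[, "tstart"]), 0L)
  info$span_end <- vapply(best$blocks, function(b) max(b[, "tend"]), 0L)
  info$five_prime <- ifelse(info$strand == "-", info$span_end,
                            info$span_start)
  ## cluster reads into preliminary loci
  ex <- do.call(rbind, lapply(seq_len(nrow(best)), function(i) {
    b <- best$blocks[[i]]
    data.frame(read = best$read_id[i], contig = best$contig[i],
               strand = info$strand[i], s = b[, "tstart"], e = b[, "tend"],
               stringsAsFactors = FALSE)
  }))
  gr <- GRanges(paste0(ex$contig, "::", ex$strand), IRanges(ex$s, ex$e))
  memb <- .cluster_by_overlap(gr, ex$read)
  info$locus <- unname(memb[info$read_id])

  jkey <- function(contig, d, a) paste(contig, d, a)
  sup_keys <- with(junction_support,
                   jkey(contig, donor, acceptor)[support_count >= 1L])
  pd <- NULL
  if (!is.null(short_reads) && length(short_reads))
    pd <- Biostrings::PDict(short_reads)

  removed_trunc <- character(0); removed_singleton <- character(0)
  for (lc in unique(info$locus)) {
    ii <- which(info$locus == lc)
    chains <- info$chain_list[ii]
    lens <- lengths(chains)
    keys <- info$chain[ii]
    for (a in seq_along(ii)) {
      ia <- ii[a]
      if (lens[a] >= 1L) {
        ## 5' truncation: strict suffix of a longer chain, 5' end downstream
        is_trunc <- FALSE
        for (b in seq_along(ii)) {
          if (b == a || lens[b] <= lens[a]) next
          tail_b <- tail(chains[[b]], lens[a])
          if (identical(tail_b, chains[[a]])) {
            downstream <- if (info$strand[ia] == "-")
              info$five_prime[ia] < info$five_prime[ii[b]]
            else info$five_prime[ia] > info$five_prime[ii[b]]
            if (downstream) { is_trunc <- TRUE; break }
          }
        }
        if (is_trunc) { removed_trunc <- c(removed_trunc, info$read_id[ia]); next }
        ## unsupported singleton (multi-exon)
        if (sum(keys == keys[a]) == 1L) {
          jk <- jkey(info$contig[ia],
                     as.integer(sub("-.*", "", chains[[a]])),
                     as.integer(sub(".*-", "", chains[[a]])))
          if (!any(jk %in% sup_keys))
            removed_singleton <- c(removed_singleton, info$read_id[ia])
        }
      } else {
        ## single-exon singleton: sole read at the locus, no short coverage
        if (length(ii) == 1L) {
          covered <- FALSE
          if (!is.null(pd) && !is.null(genome)) {
            span <- subseq(genome[[info$contig[ia]]],
                           max(1L, info$span_start[ia]), info$span_end[ia])
            covered <- sum(Biostrings::countPDict(pd, span)) > 0L
          }
          if (!covered)
            removed_singleton <- c(removed_singleton, info$read_id[ia])
        }
      }
    }
  }
  removed <- c(removed_trunc, removed_singleton)
  list(kept = setdiff(info$read_id, removed),
       removed_5prime_truncated = removed_trunc,
       removed_unsupported_singletons = removed_singleton,
       read_info = info)
}

#' Assign high-quality reads to genomic loci
#'
#' Reads are clustered by single-linkage exonic overlap (>= 1 bp, same
#' contig and strand).  A cluster is EXTANT when any of its reads shares
#' exonic overlap with an annotated gene model on the same strand, otherwise
#' NOVEL; novel clusters are additionally flagged by whether their contig
#' carries other annotated models.
#'
#' @param hq result of [filterHighQuality] (the `kept` reads are used)
#' @param models a [GeneModelSet] of draft annotation
#' @return list with `loci` (one row per locus: span, status, gene ids,
#'   support) and `reads` (read -> locus map), plus `histogram` (read
#'   support bins 1 / 2-10 / 11-100 / >100 with percentages)
#' @export
assignLoci <- function(hq, models) {
  info <- hq$read_info[hq$read_info$read_id %in% hq$kept, , drop = FALSE]
  if (!nrow(info)) stop("no reads to assign")
  ## recluster on kept reads only
  best_spans <- GRanges(paste0(info$contig, "::", info$strand),
                        IRanges(info$span_start, info$span_end))
  memb <- .cluster_by_overlap(best_spans, info$read_id)
  info$locus <- unname(memb[info$read_id])
  mex <- modelExons(models)
  mex_gr <- GRanges(paste0(as.character(seqnames(mex)), "::",
                           as.character(strand(mex))),
                    IRanges(start(mex), end(mex)))
  model_contigs <- unique(as.character(seqnames(mex)))
  loci <- lapply(split(seq_len(nrow(info)), info$locus), function(ii) {
    contig <- info$contig[ii[1]]; strand <- info$strand[ii[1]]
    s <- min(info$span_start[ii]); e <- max(info$span_end[ii])
    q <- GRanges(paste0(contig, "::", strand), IRanges(s, e))
    ov <- suppressWarnings(findOverlaps(q, mex_gr))
    gene_ids <- unique(mcols(mex)$gene_id[S4Vectors::subjectHits(ov)])
    data.frame(contig = contig, strand = strand, start = s, end = e,
               status = if (length(gene_ids)) "EXTANT" else "NOVEL",
               gene_id = if (length(gene_ids)) paste(gene_ids, collapse = ",")
                         else NA_character_,
               n_reads = length(ii),
               contig_has_other_models = contig %in% model_contigs,
               reads = I(list(info$read_id[ii])),
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, loci)
  loci$locus_id <- sprintf("L%05d", seq_len(nrow(loci)))
  rownames(loci) <- NULL
  reads <- data.frame(read_id = unlist(loci$reads),
                      locus_id = rep(loci$locus_id, lengths(loci$reads)),
                      stringsAsFactors = FALSE)
  n <- loci$n_reads
  bins <- c(`1` = sum(n == 1L), `2-10` = sum(n >= 2L & n <= 10L),
            `11-100` = sum(n >= 11L & n <= 100L), `>100` = sum(n > 100L))
  list(loci = loci, reads = reads,
       histogram = list(counts = bins,
                        percent = round(100 * bins / sum(bins), 1)))
}

#' Detect reads bridging two draft contigs
#'
#' A cross-contig read is a bridge when its two segments each align with
#' identity above `min_identity`, their inner ends fall within
#' `max_end_dist` of the respective contig ends, and the two segments
#' together cover at least `min_total_cov` percent of the read.  Bridges are
#' checked for ortholog contiguity: the read maps to a single ortholog
#' contig in one colinear piece.
#'
#' @param groups result of [classifyReadGroups] (G3 reads are examined)
#' @param aln draft-genome [SplicedAlignments]
#' @param ortholog_aln [SplicedAlignments] of the same reads against the
#'   ortholog reference genome(s)
#' @param contig_lengths named integer vector of draft contig lengths
#' @param max_end_dist maximum distance (bp) from a contig end
#' @param min_identity minimum per-segment identity (percent)
#' @param min_total_cov minimum summed segment coverage (percent)
#' @return `data.frame` of bridge records
#' @export
detectContigBridges <- function(groups, aln, ortholog_aln, contig_lengths,
                                max_end_dist = 600L, min_identity = 90,
                                min_total_cov = 80) {
  g3 <- groups$read_id[groups$group == "G3"]
  tb <- alignmentTable(aln)
  ot <- alignmentTable(ortholog_aln)
  rows <- list()
  for (rid in g3) {
    rt <- tb[tb$read_id == rid & tb$identity > min_identity, , drop = FALSE]
    if (length(unique(rt$contig)) < 2L) next
    ## best segment per contig, then the dominant non-overlapping pair on
    ## the read (homoeologous copies echo both halves at slightly lower
    ## identity; they must not make the read look "complex")
    rt <- do.call(rbind, lapply(split(rt, rt$contig), function(d)
      d[which.max(d$score), , drop = FALSE]))
    rt <- rt[order(-rt$score), , drop = FALSE]
    rl0 <- rt$read_length[1]
    ivl <- t(vapply(seq_len(nrow(rt)), function(i) {
      f <- .fwd_q(rt$blocks[[i]], rt$strand[i], rl0)
      c(min(f[, "qstart"]), max(f[, "qend"]))
    }, c(0, 0)))
    second <- which(vapply(seq_len(nrow(rt)), function(i) {
      if (i == 1L) return(FALSE)
      ov <- min(ivl[1, 2], ivl[i, 2]) - max(ivl[1, 1], ivl[i, 1]) + 1
      ov < 0.2 * (ivl[i, 2] - ivl[i, 1] + 1)
    }, TRUE))
    if (!length(second)) next
    rt <- rt[c(1L, second[1]), , drop = FALSE]
    if (sum(rt$coverage) < min_total_cov) next
    if (any(!rt$contig %in% names(contig_lengths)))
      stop("unknown contig length for ", rt$contig[1])
    ## order segments along the forward read
    rl <- rt$read_length[1]
    q <- t(vapply(seq_len(nrow(rt)), function(i) {
      f <- .fwd_q(rt$blocks[[i]], rt$strand[i], rl)
      c(min(f[, "qstart"]), max(f[, "qend"]))
    }, c(0, 0)))
    ord <- order(q[, 1])
    rt <- rt[ord, , drop = FALSE]
    ## inner end of the first segment is its read-3' side, of the second its
    ## read-5' side; translate to genomic side via the alignment orientation
    inner_dist <- numeric(2)
    for (i in 1:2) {
      b <- rt$blocks[[i]]
      clen <- contig_lengths[[rt$contig[i]]]
      at_end <- (i == 1L) == (rt$strand[i] == "+")
      inner_dist[i] <- if (at_end) clen - max(b[, "tend"])
                       else min(b[, "tstart"]) - 1L
    }
    if (any(inner_dist > max_end_dist)) next
    ## ortholog contiguity
    orow <- ot[ot$read_id == rid, , drop = FALSE]
    contiguous <- FALSE; ortctg <- NA_character_
    if (nrow(orow)) {
      ob <- orow[which.max(orow$score), , drop = FALSE]
      if (ob$coverage >= min_total_cov && ob$identity > 80) {
        contiguous <- TRUE
        ortctg <- ob$contig
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = rid, contig_a = rt$contig[1], contig_b = rt$contig[2],
      end_distance_a = inner_dist[1], end_distance_b = inner_dist[2],
      identity_a = rt$identity[1], identity_b = rt$identity[2],
      total_coverage = sum(rt$coverage),
      ortholog_contig = ortctg, ortholog_contiguous = contiguous,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(read_id = character(0), contig_a = character(0),
                      contig_b = character(0), end_distance_a = numeric(0),
                      end_distance_b = numeric(0), identity_a = numeric(0),
                      identity_b = numeric(0), total_coverage = numeric(0),
                      ortholog_contig = character(0),
                      ortholog_contiguous = logical(0)))
  do.call(rbind, rows)
}

# longest ORF (ATG..stop, same frame) in a character sequence; returns
# c(start, end) 1-based inclusive of stop codon, or NULL
.longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- NULL; bestlen <- 0L
  codons <- function(from) {
    ix <- seq(from, n - 2L, by = 3L)
    substring(seq, ix, ix + 2L)
  }
  for (frame in 0:2) {
    if (n - frame < 6L) next
    cod <- codons(frame + 1L)
    stops <- which(cod %in% c("TAA", "TAG", "TGA"))
    starts <- which(cod == "ATG")
    if (!length(stops) || !length(starts)) next
    prev_stop <- 0L
    for (s in stops) {
      cand <- starts[starts > prev_stop & starts < s]
      if (length(cand)) {
        len <- (s - cand[1] + 1L) * 3L
        if (len > bestlen) {
          bestlen <- len
          best <- c(frame + 1L + (cand[1] - 1L) * 3L,
                    frame + (s * 3L))
        }
      }
      prev_stop <- s
    }
  }
  best
}

# map a transcript-coordinate position through alignment blocks to a genomic
# position; q coords of blocks are on the aligned orientation
.tx_to_genome <- function(blocks, strand, read_length, pos) {
  p <- if (strand == "-") read_length - pos + 1L else pos
  for (i in seq_len(nrow(blocks))) {
    if (p >= blocks[i, "qstart"] && p <= blocks[i, "qend"])
      return(blocks[i, "tstart"] + (p - blocks[i, "qstart"]))
  }
  NA_integer_
}

#' Detect transcripts spanning multiple annotated gene models
#'
#' A transcript is a merge candidate when its exons overlap the exons of two
#' or three annotated models on one contig with a unique, positive alignment
#' (identity and coverage > 90).  It is VALIDATED when it also maps reliably
#' (>= 80/80) to an orthologous genomic region annotated with exactly one
#' gene.
#'
#' @param transcripts `data.frame` with one row per transcript:
#'   `transcript_id`, `contig`, `strand`, `coverage`, `identity` and a
#'   `blocks` list column (e.g. representative-read alignments from
#'   [collapseIsoforms])
#' @param models draft [GeneModelSet]
#' @param ortholog_aln [SplicedAlignments] of the transcripts'
#'   representative sequences against an ortholog genome
#' @param ortholog_models [GeneModelSet] of the ortholog genome
#' @param sequences optional named `DNAStringSet` of transcript sequences
#'   (for ORF length)
#' @return `data.frame` of merge candidates
#' @export
detectSpanningTranscripts <- function(transcripts, models, ortholog_aln,
                                      ortholog_models, sequences = NULL) {
  mex <- modelExons(models)
  mex_gr <- GRanges(paste0(as.character(seqnames(mex)), "::",
                           as.character(strand(mex))),
                    IRanges(start(mex), end(mex)))
  oex <- modelExons(ortholog_models)
  ospan <- geneSpans(ortholog_models)
  ot <- alignmentTable(ortholog_aln)
  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, , drop = FALSE]
    if (is.na(tr$coverage) || tr$coverage <= 90 || tr$identity <= 90) next
    b <- tr$blocks[[1]]
    q <- GRanges(rep(paste0(tr$contig, "::", tr$strand), nrow(b)),
                 IRanges(b[, "tstart"], b[, "tend"]))
    ov <- suppressWarnings(findOverlaps(q, mex_gr))
    genes <- unique(mcols(mex)$gene_id[S4Vectors::subjectHits(ov)])
    if (length(genes) < 2L || length(genes) > 3L) next
    ## ortholog validation
    status <- "UNVALIDATED"; oid <- NA_real_; octg <- NA_character_
    orow <- ot[ot$read_id == tr$transcript_id, , drop = FALSE]
    orow <- orow[orow$coverage >= 80 & orow$identity >= 80, , drop = FALSE]
    if (nrow(orow)) {
      ob <- orow[which.max(orow$score), , drop = FALSE]
      sp <- GRanges(ob$contig,
                    IRanges(min(ob$blocks[[1]][, "tstart"]),
                            max(ob$blocks[[1]][, "tend"])))
      og <- GRanges(as.character(seqnames(ospan)),
                    IRanges(start(ospan), end(ospan)))
      n_genes <- length(unique(
        mcols(ospan)$gene_id[S4Vectors::subjectHits(suppressWarnings(findOverlaps(sp, og)))]))
      if (n_genes == 1L) { status <- "VALIDATED"; oid <- ob$identity
                           octg <- ob$contig }
    }
    orf_aa <- NA_integer_
    if (!is.null(sequences) && tr$transcript_id %in% names(sequences)) {
      orf <- .longest_orf(as.character(sequences[[tr$transcript_id]]))
      if (!is.null(orf)) orf_aa <- as.integer((orf[2] - orf[1] + 1L) / 3L - 1L)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = tr$transcript_id, contig = tr$contig,
      spanned_gene_ids = paste(sort(genes), collapse = ","),
      n_spanned = length(genes), orf_length_aa = orf_aa,
      ortholog_validation = status, ortholog_identity = oid,
      ortholog_contig = octg, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(transcript_id = character(0), contig = character(0),
                      spanned_gene_ids = character(0), n_spanned = integer(0),
                      orf_length_aa = integer(0),
                      ortholog_validation = character(0),
                      ortholog_identity = numeric(0),
                      ortholog_contig = character(0)))
  do.call(rbind, rows)
}

#' Rescue poorly mapped reads against ortholog gene sets
#'
#' Aligns each read to candidate genes of related diploid species (selected
#' by shared k-mers, scored by banded global alignment).  A read is rescued
#' when its best alignment to a gene reaches coverage and identity above 90
#' percent; ties go to the higher score, then the lexicographically first
#' gene id.
#'
#' @param reads named `DNAStringSet` (typically G4/G5 reads)
#' @param gene_sets named list of `DNAStringSet` (one per species)
#' @param min_cov,min_id rescue thresholds (percent)
#' @return list with `matches` (per read and species: best gene, coverage,
#'   identity, rescued flag) and `counts` (rescued reads per species)
#' @export
rescueUnmapped <- function(reads, gene_sets, min_cov = 90, min_id = 90) {
  if (!length(gene_sets) || any(!vapply(gene_sets, length, 0L)))
    if (any(vapply(gene_sets, length, 0L) == 0L)) stop("empty gene set")
  rows <- list()
  for (sp in names(gene_sets)) {
    gs <- as.character(gene_sets[[sp]])
    for (ri in seq_along(reads)) {
      r <- as.character(reads[[ri]])
      shared <- vapply(gs, function(g) kmer_overlap_cpp(r, g, 15L), 0L)
      cand <- order(shared, decreasing = TRUE)
      cand <- cand[shared[cand] >= 10L][seq_len(min(3L, sum(shared >= 10L)))]
      best <- NULL
      for (ci in cand) {
        al <- banded_global_cpp(r, gs[ci],
                                max(60L, abs(nchar(r) - nchar(gs[ci])) + 80L))
        cov <- 100 * (al$nmatch + al$nmismatch) / nchar(r)
        ident <- 100 * al$nmatch /
          (al$nmatch + al$nmismatch + al$nins + al$ndel)
        sc <- cov * ident / 100
        if (is.null(best) || sc > best$sc ||
            (sc == best$sc && names(gene_sets[[sp]])[ci] < best$gene)) {
          best <- list(gene = names(gene_sets[[sp]])[ci], cov = cov,
                       id = ident, sc = sc)
        }
      }
      if (!is.null(best)) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = names(reads)[ri], species = sp, gene_id = best$gene,
          coverage = best$cov, identity = best$id,
          rescued = best$cov > min_cov && best$id > min_id,
          stringsAsFactors = FALSE)
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), species = character(0),
               gene_id = character(0), coverage = numeric(0),
               identity = numeric(0), rescued = logical(0))
  counts <- vapply(names(gene_sets), function(sp)
    sum(matches$rescued[matches$species == sp]), 0L)
  list(matches = matches, counts = counts)
}

#' Estimate the proportion of reads carrying a complete ORF
#'
#' Loci covered by both a reference full-length cDNA and at least one read
#' are identified by exonic overlap.  A read at such a locus is complete
#' when its genomic span contains both the start-codon and the stop-codon
#' genomic positions of the co-located cDNA's ORF (genomic-span containment,
#' robust to residual read errors).  cDNAs without a detectable ORF are
#' excluded with a warning.
#'
#' @param read_aln best-per-read draft [SplicedAlignments] of the FLNC reads
#' @param cdna_aln [SplicedAlignments] of the reference cDNAs on the same
#'   genome
#' @param cdnas named `DNAStringSet` of the reference cDNAs
#' @return list with `n_complete`, `n_total`, `percent` (1 decimal) and the
#'   per-read table
#' @export
estimateOrfCompleteness <- function(read_aln, cdna_aln, cdnas) {
  ct <- alignmentTable(cdna_aln)
  rt <- if (is(read_aln, "SplicedAlignments")) .best_per_read(read_aln)
        else read_aln
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(ct))) {
    cid <- ct$read_id[i]
    if (!cid %in% names(cdnas)) next
    orf <- .longest_orf(as.character(cdnas[[cid]]))
    if (is.null(orf)) { skipped <- skipped + 1L; next }
    b <- ct$blocks[[i]]
    gstart <- .tx_to_genome(b, ct$strand[i], ct$read_length[i], orf[1])
    gstop <- .tx_to_genome(b, ct$strand[i], ct$read_length[i], orf[2])
    if (is.na(gstart) || is.na(gstop)) next
    lo <- min(gstart, gstop); hi <- max(gstart, gstop)
    ## reads at this locus: exonic overlap with the cDNA alignment span
    cspan <- c(min(b[, "tstart"]), max(b[, "tend"]))
    hits <- rt[rt$contig == ct$contig[i], , drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      rb <- hits$blocks[[j]]
      if (max(rb[, "tend"]) < cspan[1] || min(rb[, "tstart"]) > cspan[2])
        next
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = hits$read_id[j], cdna_id = cid,
        complete = min(rb[, "tstart"]) <= lo && max(rb[, "tend"]) >= hi,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped) warning(skipped, " reference cDNAs without detectable ORF ",
                       "excluded")
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), cdna_id = character(0),
               complete = logical(0))
  ## a read may sit at a locus with several cDNAs: complete if complete
  ## against any co-located cDNA
  if (nrow(tab)) {
    agg <- tapply(tab$complete, tab$read_id, any)
    n_total <- length(agg); n_complete <- sum(agg)
  } else { n_total <- 0L; n_complete <- 0L }
  list(n_complete = n_complete, n_total = n_total,
       percent = if (n_total) round(100 * n_complete / n_total, 1)
                 else NA_real_,
       table = tab)
}
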