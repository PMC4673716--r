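## Stage-wise expression: short-read evidence (exact matching against
## spliced transcript sequences extracted from the genome), RPKM-based
## expressed-gene calling, and junction-based isoform presence and
## differential tables.

# spliced sequence and junction layout of a transcript model given its
# genomic exon blocks (ascending); returns seq, cumulative exon ends
# (junction positions in transcript coordinates, sense orientation) and
# junction genomic keys
.spliced_tx <- function(genome, contig, strand, exons) {
  ex <- exons[order(exons[, 1]), , drop = FALSE]
  seqs <- vapply(seq_len(nrow(ex)), function(i)
    as.character(subseq(genome[[contig]], ex[i, 1], ex[i, 2])), "")
  s <- paste(seqs, collapse = "")
  cums <- cumsum(ex[, 2] - ex[, 1] + 1L)
  jkeys <- if (nrow(ex) > 1L)
    sprintf("%s:%d-%d", contig, ex[-nrow(ex), 2] + 1L, ex[-1L, 1] - 1L)
  else character(0)
  jpos <- head(cums, -1L)                 # position of last base before gap
  if (strand == "-") {
    s <- .revcomp_chr(s)
    jpos <- nchar(s) - jpos               # still the base before the gap
    ord <- order(jpos)
    jpos <- jpos[ord]; jkeys <- jkeys[ord]
  }
  list(seq = s, jpos = jpos, jkeys = jkeys)
}

#' Short-read evidence against a transcript catalogue
#'
#' Matches (error-tolerance-free, exact) each stage's short reads against the
#' spliced transcript sequences extracted from the genome for the given
#' models, in both orientations.  Produces per-stage junction support, gene
#' assignment counts (a read counts for a gene only when all its transcript
#' matches belong to that one gene -- the strict unique-overlap rule) and
#' library sizes.
#'
#' @param short_reads_by_stage named list of `DNAStringSet` (one per stage)
#' @param tx_table `data.frame` with `transcript_id`, `gene_id`, `contig`,
#'   `strand` and a `blocks` list column of genomic exon blocks
#' @param genome named `DNAStringSet`
#' @param min_overhang bases a read must extend past a junction on both
#'   sides to support it
#' @return list with per-stage `junction_support` (key -> count),
#'   `gene_counts`, `library_size` (uniquely assigned reads), pooled
#'   `junctions` table, and `tx_index`
#' @export
shortReadEvidence <- function(short_reads_by_stage, tx_table, genome,
                              min_overhang = 8L) {
  ## build transcript sequences
  txs <- lapply(seq_len(nrow(tx_table)), function(i) {
    b <- tx_table$blocks[[i]]
    ex <- cbind(b[, "tstart"], b[, "tend"])
    .spliced_tx(genome, tx_table$contig[i], tx_table$strand[i], ex)
  })
  names(txs) <- tx_table$transcript_id
  gene_of <- setNames(tx_table$gene_id, tx_table$transcript_id)
  stages <- names(short_reads_by_stage)
  res <- list()
  for (st in stages) {
    reads <- short_reads_by_stage[[st]]
    jsup <- numeric(0)
    gcount <- numeric(0)
    nuniq <- 0L
    if (length(reads)) {
      L <- unique(Biostrings::nchar(reads))
      stopifnot(length(L) == 1L)
      pd <- Biostrings::PDict(reads)
      pdr <- Biostrings::PDict(reverseComplement(reads))
      parts <- list()
      for (ti in seq_along(txs)) {
        tx <- txs[[ti]]
        if (nchar(tx$seq) < L) next
        subject <- DNAString(tx$seq)
        for (orient in 1:2) {
          m <- Biostrings::matchPDict(if (orient == 1L) pd else pdr, subject)
          cnt <- S4Vectors::elementNROWS(m)
          hit <- which(cnt > 0L)
          if (!length(hit)) next
          parts[[length(parts) + 1L]] <- data.table(
            ti = ti, ri = rep(hit, cnt[hit]),
            start = unlist(Biostrings::startIndex(m)[hit],
                           use.names = FALSE))
        }
      }
      if (length(parts)) {
        big <- rbindlist(parts)
        ## junction support uses uniquely mapped reads only: a read matching
        ## transcripts at more than one locus (e.g. a clean window shared
        ## with a homoeologous copy) supports nothing
        locus_of <- if (!is.null(tx_table$locus_group))
          setNames(tx_table$locus_group, tx_table$transcript_id)
        else gene_of
        rl <- unique(data.table(ri = big$ri,
                                loc = unname(locus_of[
                                  tx_table$transcript_id[big$ti]])))
        nl <- rl[, .N, by = ri]
        uniq_loc <- nl$ri[nl$N == 1L]
        bigu <- big[ri %in% uniq_loc]
        jl <- list()
        for (ti in unique(bigu$ti)) {
          tx <- txs[[ti]]
          if (!length(tx$jpos)) next
          s0 <- sort(bigu$start[bigu$ti == ti])
          for (jj in seq_along(tx$jpos)) {
            lo <- tx$jpos[jj] - L + 1L + min_overhang
            hi <- tx$jpos[jj] - min_overhang + 1L
            cnt <- sum(s0 >= lo & s0 <= hi)
            if (cnt > 0L)
              jl[[length(jl) + 1L]] <- data.table(jk = tx$jkeys[jj],
                                                  cnt = cnt)
          }
        }
        if (length(jl)) {
          agg <- rbindlist(jl)[, .(cnt = sum(cnt)), by = "jk"]
          jsup <- setNames(agg$cnt, agg$jk)
        }
        ## gene assignment: unique exonic (transcript) overlap only
        rg <- unique(data.table(ri = big$ri,
                                gene = unname(gene_of[tx_table$transcript_id[
                                  big$ti]])))
        ng <- rg[, .N, by = ri]
        uniq <- ng$ri[ng$N == 1L]
        nuniq <- length(uniq)
        gc <- rg[ri %in% uniq][, .N, by = gene]
        gcount <- setNames(gc$N, gc$gene)
      }
    }
    res[[st]] <- list(junction_support = jsup,
                      gene_counts = gcount,
                      library_size = nuniq)
  }
  ## pooled junction table
  allk <- unique(unlist(lapply(res, function(x) names(x$junction_support))))
  pooled <- setNames(rep(0L, length(allk)), allk)
  for (st in stages) {
    js <- res[[st]]$junction_support
    pooled[names(js)] <- pooled[names(js)] + js
  }
  jt <- if (length(pooled)) {
    parts <- regmatches(names(pooled),
                        regexec("^(.*):(\\d+)-(\\d+)$", names(pooled)))
    data.frame(contig = vapply(parts, `[`, "", 2),
               donor = as.integer(vapply(parts, `[`, "", 3)),
               acceptor = as.integer(vapply(parts, `[`, "", 4)),
               support_count = as.integer(pooled),
               stringsAsFactors = FALSE)
  } else data.frame(contig = character(0), donor = integer(0),
                    acceptor = integer(0), support_count = integer(0))
  list(stages = res, junctions = jt)
}

#' RPKM of one gene at one stage
#'
#' `rpkm = exon_reads / (mapped_reads_in_millions * exon_length_in_kb)`.
#'
#' @param exon_reads short reads uniquely assigned to the gene's exons
#' @param library_size total uniquely mapped reads of the stage library
#' @param exon_length_bp summed exon length of the gene in bp
#' @return the RPKM value
#' @export
computeRpkm <- function(exon_reads, library_size, exon_length_bp) {
  if (exon_length_bp <= 0) stop("zero exon length")
  if (library_size <= 0) stop("empty library")
  exon_reads / ((library_size / 1e6) * (exon_length_bp / 1e3))
}

#' Stage-wise expressed-gene calling
#'
#' A gene is expressed at a stage when its RPKM is strictly greater than
#' `threshold` (RPKM exactly at the threshold does not count).
#'
#' @param evidence result of [shortReadEvidence]
#' @param gene_lengths named vector of summed exon lengths (bp) per gene
#' @param threshold RPKM threshold (strict)
#' @return list with per-stage `rpkm` tables and `expressed` gene-id sets
#' @export
callExpressedGenes <- function(evidence, gene_lengths, threshold = 1) {
  out_r <- list(); out_e <- list()
  for (st in names(evidence$stages)) {
    ev <- evidence$stages[[st]]
    genes <- names(gene_lengths)
    cnt <- ev$gene_counts[genes]
    cnt[is.na(cnt)] <- 0L
    rpkm <- if (ev$library_size > 0)
      vapply(seq_along(genes), function(i)
        computeRpkm(cnt[i], ev$library_size, gene_lengths[[genes[i]]]), 0)
    else rep(0, length(genes))
    tab <- data.frame(gene_id = genes, stage = st, exon_reads = unname(cnt),
                      library_size = ev$library_size,
                      exon_length_kb = unname(gene_lengths[genes]) / 1e3,
                      rpkm = rpkm, stringsAsFactors = FALSE)
    out_r[[st]] <- tab
    out_e[[st]] <- genes[rpkm > threshold]
  }
  list(rpkm = out_r, expressed = out_e)
}

#' Junction-based isoform presence per stage
#'
#' An isoform's specific junctions are those present in its chain and absent
#' from every sibling isoform's chain at the same locus.  The isoform is
#' present at a stage when at least one specific junction is covered by one
#' or more short reads of that stage.  Isoforms without any specific
#' junction (including single-exon isoforms) are UNRESOLVABLE and excluded
#' from differential calling.
#'
#' @param isoforms result of [collapseIsoforms]
#' @param evidence result of [shortReadEvidence]
#' @return `data.frame`: one row per isoform and stage with `present`;
#'   attribute `"unresolvable"` lists the excluded isoform ids
#' @export
isoformPresence <- function(isoforms, evidence) {
  iso <- isoforms
  iso$jkeys <- lapply(seq_len(nrow(iso)), function(i) {
    if (!nzchar(iso$chain[i])) return(character(0))
    sprintf("%s:%s", iso$contig[i], strsplit(iso$chain[i], ";")[[1]])
  })
  specific <- vector("list", nrow(iso))
  for (lc in unique(iso$locus_id)) {
    ii <- which(iso$locus_id == lc)
    for (a in ii) {
      sib <- unlist(iso$jkeys[setdiff(ii, a)])
      specific[[a]] <- setdiff(iso$jkeys[[a]], sib)
    }
  }
  unres <- iso$transcript_id[lengths(specific) == 0L]
  stages <- names(evidence$stages)
  rows <- list()
  for (i in seq_len(nrow(iso))) {
    if (!length(specific[[i]])) next
    for (st in stages) {
      js <- evidence$stages[[st]]$junction_support
      sup <- sum(js[specific[[i]]], na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = iso$transcript_id[i], locus_id = iso$locus_id[i],
        stage = st, supporting_reads = sup, present = sup >= 1L,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), locus_id = character(0),
               stage = character(0), supporting_reads = integer(0),
               present = logical(0))
  attr(res, "unresolvable") <- unres
  res
}

#' Differential isoform table
#'
#' A locus (gene) is differential when any of its resolvable isoforms has a
#' presence vector that is not constant across the stages.  Isoforms are
#' labelled alphabetically per locus ("a", "b", ...) by descending read
#' support.
#'
#' @param presence result of [isoformPresence]
#' @param isoforms result of [collapseIsoforms] (for support-based labels)
#' @return `data.frame`: one row per locus with `differential`,
#'   `n_isoforms` and per-isoform presence patterns like "a:1101"
#' @export
differentialIsoformTable <- function(presence, isoforms) {
  if (!nrow(presence))
    return(data.frame(locus_id = character(0), differential = logical(0),
                      n_isoforms = integer(0), patterns = character(0)))
  support <- setNames(isoforms$n_supporting_reads, isoforms$transcript_id)
  stages <- unique(presence$stage)
  rows <- list()
  for (lc in unique(presence$locus_id)) {
    pp <- presence[presence$locus_id == lc, , drop = FALSE]
    txids <- unique(pp$transcript_id)
    txids <- txids[order(-support[txids], txids)]
    pats <- vapply(txids, function(tx) {
      sub <- pp[pp$transcript_id == tx, , drop = FALSE]
      v <- sub$present[match(stages, sub$stage)]
      paste(as.integer(v), collapse = "")
    }, "")
    lab <- letters[seq_along(txids)]
    diff <- any(vapply(pats, function(p) {
      ch <- strsplit(p, "")[[1]]; length(unique(ch)) > 1L
    }, TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = lc, differential = diff, n_isoforms = length(txids),
      patterns = paste(sprintf("%s:%s", lab, pats), collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
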