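## Partition mapped reads into the five mapping groups, analyse
## multi-mapping patterns across subgenomes, and validate splice junctions
## against short-read evidence.

#' Classification thresholds
#'
#' The published band definitions: G1 = unique best alignment with coverage
#' and identity both above 90 (strict); G2 = two or more tied best
#' alignments at 90 or above; G3 = partial mapping (coverage 30-80,
#' identity >= 90) on two or more contigs; G4 = any remaining significant
#' alignment (identity >= 40, coverage >= 30); G5 = none.  The bands leave
#' gaps, so the cascade order makes G4 the catch-all: the five groups then
#' exhaust every read, as the published totals do.
#'
#' @param g1_min strict lower bound for G1 coverage and identity
#' @param g2_min inclusive bound for tied best alignments
#' @param g2_mode "and" requires both metrics >= `g2_min` on the tied
#'   alignments, "or" either (the published wording is ambiguous)
#' @param g3_cov coverage band (inclusive) for cross-contig partial mapping
#' @param g3_min_id minimum identity for G3 segments
#' @param g4_min_id,g4_min_cov floor of "significant mapping"
#' @param tie_delta score difference treated as a tie
#' @return list of class `ClassifyThresholds`
#' @export
classifyThresholds <- function(g1_min = 90, g2_min = 90,
                               g2_mode = c("and", "or"),
                               g3_cov = c(30, 80), g3_min_id = 90,
                               g4_min_id = 40, g4_min_cov = 30,
                               tie_delta = 0.1) {
  g2_mode <- match.arg(g2_mode)
  structure(list(g1_min = g1_min, g2_min = g2_min, g2_mode = g2_mode,
                 g3_cov = g3_cov, g3_min_id = g3_min_id,
                 g4_min_id = g4_min_id, g4_min_cov = g4_min_cov,
                 tie_delta = tie_delta),
            class = "ClassifyThresholds")
}

#' Classify reads into mapping groups G1-G5
#'
#' Applies the ordered cascade: (0) reads whose alignment direction cannot
#' be determined are set aside as UNDETERMINED; (1) a unique best alignment
#' with coverage > 90 and identity > 90 is G1; (2) two or more tied best
#' alignments at distinct loci meeting the G2 bound are G2; (3) partial
#' alignments (identity >= 90, coverage 30-80) on two or more contigs are
#' G3; (4) any remaining alignment with identity >= 40 and coverage >= 30 is
#' G4; (5) everything else, including reads with no alignment, is G5.
#' Every read is assigned exactly once and the result is independent of
#' input order.
#'
#' @param aln a [SplicedAlignments] for all reads
#' @param genome named `DNAStringSet` of contigs (for strand motifs)
#' @param read_ids ids of all reads to classify (reads absent from `aln`
#'   become G5)
#' @param thresholds a [classifyThresholds]
#' @return `data.frame` with `read_id`, `group`, `strand`, plus the
#'   alignment evidence table as attribute `"evidence"`
#' @export
classifyReadGroups <- function(aln, genome, read_ids = NULL,
                               thresholds = classifyThresholds()) {
  tb <- alignmentTable(aln)
  if (is.null(read_ids)) read_ids <- unique(tb$read_id)
  th <- thresholds
  bylist <- split(seq_len(nrow(tb)), tb$read_id)
  out <- vector("list", length(read_ids))
  for (i in seq_along(read_ids)) {
    rid <- read_ids[i]
    ii <- bylist[[rid]]
    if (is.null(ii)) {
      out[[i]] <- data.frame(read_id = rid, group = "G5",
                             strand = NA_character_,
                             stringsAsFactors = FALSE)
      next
    }
    rt <- tb[ii, , drop = FALSE]
    sel <- selectBestLocus(rt, tie_delta = th$tie_delta)
    best <- sel$best
    strand <- determineStrand(best, genome,
                              both_orient_scores =
                                rt$score[rt$contig == best$contig],
                              tie_delta = th$tie_delta)
    grp <- NULL
    if (strand == "?") {
      grp <- "UNDETERMINED"
    } else {
      tied_loci <- length(unique(sel$tied$contig))
      if (!sel$ambiguous || tied_loci < 2L) {
        if (best$coverage > th$g1_min && best$identity > th$g1_min)
          grp <- "G1"
      } else {
        pass <- if (th$g2_mode == "and")
          sel$tied$identity >= th$g2_min & sel$tied$coverage >= th$g2_min
        else sel$tied$identity >= th$g2_min | sel$tied$coverage >= th$g2_min
        if (sum(pass) >= 2L) grp <- "G2"
      }
      if (is.null(grp)) {
        g3ok <- rt$identity >= th$g3_min_id &
          rt$coverage >= th$g3_cov[1] & rt$coverage <= th$g3_cov[2]
        if (length(unique(rt$contig[g3ok])) >= 2L) grp <- "G3"
      }
      if (is.null(grp)) {
        if (any(rt$identity >= th$g4_min_id &
                  rt$coverage >= th$g4_min_cov)) grp <- "G4"
      }
      if (is.null(grp)) grp <- "G5"
    }
    out[[i]] <- data.frame(read_id = rid, group = grp, strand = strand,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$read_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "evidence") <- tb
  res
}

#' Map contig names to subgenomes
#'
#' Contigs are named after chromosome arms (e.g. "1AL_00017"): the second
#' character is the subgenome letter.
#'
#' @param contigs character vector of contig names
#' @return named character vector contig -> subgenome (NA when not parsable)
#' @export
contigSubgenomeMap <- function(contigs) {
  sub <- substr(contigs, 2L, 2L)
  sub[!sub %in% c("A", "B", "D")] <- NA_character_
  setNames(sub, contigs)
}

#' Multi-mapping pattern analysis of G2 reads
#'
#' Partitions multi-mapping reads into the three published patterns: one
#' best alignment in each of two or three subgenomes (homoeologs); multiple
#' locations within a single subgenome (paralogs); or multiple subgenomes
#' with multiplicity in at least one.
#'
#' @param groups result of [classifyReadGroups]
#' @param contig_to_subgenome named vector contig -> subgenome (see
#'   [contigSubgenomeMap])
#' @param thresholds a [classifyThresholds] (for the tie rule)
#' @return `data.frame` with `read_id`, `pattern`, `subgenomes_hit`;
#'   reads touching contigs with unknown subgenome are flagged
#'   `UNKNOWN_SUBGENOME` with a warning
#' @export
g2PatternAnalysis <- function(groups, contig_to_subgenome,
                              thresholds = classifyThresholds()) {
  ev <- attr(groups, "evidence")
  g2 <- groups$read_id[groups$group == "G2"]
  out <- vector("list", length(g2))
  n_unknown <- 0L
  for (i in seq_along(g2)) {
    rt <- ev[ev$read_id == g2[i], , drop = FALSE]
    sel <- selectBestLocus(rt, tie_delta = thresholds$tie_delta)
    sg <- unname(contig_to_subgenome[sel$tied$contig])
    if (anyNA(sg)) {
      n_unknown <- n_unknown + 1L
      out[[i]] <- data.frame(read_id = g2[i], pattern = "UNKNOWN_SUBGENOME",
                             subgenomes_hit = NA_character_,
                             stringsAsFactors = FALSE)
      next
    }
    cnt <- table(sg)
    pattern <- if (length(cnt) >= 2L && all(cnt == 1L))
      "ONE_BEST_PER_SUBGENOME"
    else if (length(cnt) == 1L) "MULTI_WITHIN_ONE_SUBGENOME"
    else "MULTI_ACROSS_SUBGENOMES"
    out[[i]] <- data.frame(read_id = g2[i], pattern = pattern,
                           subgenomes_hit = paste(sort(names(cnt)),
                                                  collapse = "/"),
                           stringsAsFactors = FALSE)
  }
  if (n_unknown) warning(n_unknown, " G2 reads hit contigs with unknown ",
                         "subgenome")
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(read_id = character(0), pattern = character(0),
                      subgenomes_hit = character(0))
  res
}

.classify_motif <- function(m) {
  ifelse(m %in% c("GT-AG", "GC-AG", "AT-AC"), m, "other")
}

#' Extract splice junctions from blocked alignments
#'
#' One junction per inter-block genomic gap of at least `min_intron` bases.
#' `donor` and `acceptor` are the first and last intronic base in forward
#' genome coordinates; the motif is the donor dinucleotide plus acceptor
#' dinucleotide, strand-adjusted, classified as GT-AG / GC-AG / AT-AC /
#' other.
#'
#' @param aln a [SplicedAlignments]
#' @param genome named `DNAStringSet` of contigs
#' @param min_intron smallest genomic gap regarded as a junction
#' @return `data.frame` with `read_id, contig, donor, acceptor, strand,
#'   motif`
#' @export
extractJunctions <- function(aln, genome, min_intron = 40L) {
  tb <- alignmentTable(aln)
  gseq <- as.character(genome)
  rows <- list()
  for (i in seq_len(nrow(tb))) {
    b <- tb$blocks[[i]]
    if (nrow(b) < 2L) next
    g <- gseq[[tb$contig[i]]]
    for (j in seq_len(nrow(b) - 1L)) {
      donor <- b[j, "tend"] + 1L
      acceptor <- b[j + 1L, "tstart"] - 1L
      if (acceptor - donor + 1L < min_intron) next
      d2 <- substr(g, donor, donor + 1L)
      a2 <- substr(g, acceptor - 1L, acceptor)
      fwd <- paste0(d2, "-", a2)
      rev <- paste0(.revcomp_chr(a2), "-", .revcomp_chr(d2))
      if (fwd %in% c("GT-AG", "GC-AG", "AT-AC")) {
        strand <- "+"; motif <- fwd
      } else if (rev %in% c("GT-AG", "GC-AG", "AT-AC")) {
        strand <- "-"; motif <- rev
      } else {
        strand <- tb$strand[i]
        motif <- "other"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = tb$read_id[i], contig = tb$contig[i], donor = donor,
        acceptor = acceptor, strand = strand, motif = motif,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(read_id = character(0), contig = character(0),
                      donor = integer(0), acceptor = integer(0),
                      strand = character(0), motif = character(0)))
  do.call(rbind, rows)
}

#' Validate long-read junctions against short-read junctions
#'
#' A long-read junction is supported when an identical junction (same
#' contig, donor, acceptor and strand) occurs in the short-read set with
#' support of at least one read.
#'
#' @param long_junctions `data.frame` from [extractJunctions]
#' @param short_junctions `data.frame` with `contig, donor, acceptor,
#'   strand, support_count` (see [readJunctionsBED])
#' @return list with `junctions` (input plus `supported` flag),
#'   `supported_fraction` and `motif_table` (distinct-junction motif
#'   frequencies, percentages)
#' @export
validateJunctions <- function(long_junctions, short_junctions) {
  lj <- long_junctions
  key <- function(d) paste(d$contig, d$donor, d$acceptor, d$strand)
  sj <- short_junctions[short_junctions$support_count >= 1L, , drop = FALSE]
  lj$supported <- key(lj) %in% key(sj)
  uj <- lj[!duplicated(key(lj)), , drop = FALSE]
  mt <- table(.classify_motif(uj$motif))
  list(junctions = lj,
       supported_fraction = if (nrow(lj)) mean(lj$supported) else NA_real_,
       motif_table = round(100 * mt / sum(mt), 2))
}
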