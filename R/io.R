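## Readers/writers for the standard formats the pipeline touches.  One
## coordinate convention internally (1-based, closed, IRanges style);
## conversion happens only here, at the format boundary.  PSL is 0-based
## half-open, GFF3 and BED are converted likewise.

#' Read a FASTA file with validation
#'
#' Wraps [Biostrings::readDNAStringSet] with the up-front checks a pipeline
#' input deserves: non-empty unique headers and non-empty sequences, with
#' parse errors naming the offending line.  Sequences are uppercased and
#' returned in file order.
#'
#' @param path path to a FASTA file
#' @return a `DNAStringSet`
#' @export
readFastaSeqs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(lines) && !length(hdr))
    stop("not FASTA (no '>' header): ", path)
  if (length(hdr)) {
    if (hdr[1] != 1L && any(nzchar(trimws(lines[seq_len(hdr[1] - 1L)]))))
      stop("sequence before first header at line 1 in ", path)
    ids <- sub("^>\\s*(\\S*).*$", "\\1", lines[hdr])
    bad <- which(!nzchar(ids))
    if (length(bad))
      stop("malformed empty header at line ", hdr[bad[1]], " in ", path)
    dup <- which(duplicated(ids))
    if (length(dup))
      stop("duplicate id '", ids[dup[1]], "' at line ", hdr[dup[1]],
           " in ", path)
    ends <- c(hdr[-1] - 1L, length(lines))
    nseq <- ends - hdr
    empty <- which(nseq < 1L |
                     !nzchar(vapply(seq_along(hdr), function(i) {
                       paste(trimws(lines[seq(hdr[i] + 1L,
                                              length.out = nseq[i])]),
                             collapse = "")
                     }, "")))
    if (length(empty))
      stop("empty sequence for '", ids[empty[1]], "' at line ",
           hdr[empty[1]], " in ", path)
  }
  x <- readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(x))
}

#' Read a FASTQ file
#'
#' @param path path to a FASTQ file
#' @return a `DNAStringSet` (qualities are not retained; the pipeline uses a
#'   flat quality model)
#' @export
readFastqSeqs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- readDNAStringSet(path, format = "fastq")
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences as FASTA or FASTQ
#' @param seqs named `DNAStringSet`
#' @param path output path
#' @param format "fasta" or "fastq" (flat qualities)
#' @return `path`, invisibly
#' @export
writeSeqs <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeXStringSet(seqs, path)
  } else {
    q <- Biostrings::BStringSet(vapply(Biostrings::nchar(seqs), function(n)
      paste(rep("I", n), collapse = ""), ""))
    writeXStringSet(seqs, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

.parse_gff_attrs <- function(a) {
  kv <- strsplit(a, ";", fixed = TRUE)
  lapply(kv, function(x) {
    x <- x[nzchar(x)]
    parts <- regmatches(x, regexpr("=", x), invert = TRUE)
    vals <- vapply(parts, function(p) if (length(p) == 2) p[2] else "", "")
    names(vals) <- vapply(parts, `[`, "", 1)
    vals
  })
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`/`mRNA`/`exon` features into a [GeneModelSet].  GFF3 1-based
#' inclusive coordinates map directly onto the internal IRanges convention.
#' Exons must name an mRNA parent, mRNAs a gene parent; features with strand
#' "." are rejected.
#'
#' @param path path to a GFF3 file
#' @return a `GeneModelSet`
#' @export
readGeneModelsGFF3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  if (!length(lines)) return(GeneModelSet())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L))
    stop("malformed GFF3 (need 9 tab-separated columns): ", path)
  f <- do.call(rbind, f)
  type <- f[, 3]
  attrs <- .parse_gff_attrs(f[, 9])
  getattr <- function(i, key) {
    v <- attrs[[i]][key]
    if (is.na(v)) NA_character_ else unname(v)
  }
  mrna <- which(type == "mRNA")
  exon <- which(type == "exon")
  mrna_id <- vapply(mrna, getattr, "", key = "ID")
  mrna_parent <- vapply(mrna, getattr, "", key = "Parent")
  names(mrna_parent) <- mrna_id
  ex_parent <- vapply(exon, getattr, "", key = "Parent")
  if (any(is.na(ex_parent)))
    stop("exon without Parent in ", path)
  unknown <- setdiff(ex_parent, mrna_id)
  if (length(unknown))
    stop("exon parent not an mRNA: ", unknown[1], " in ", path)
  strand <- f[exon, 7]
  if (any(!strand %in% c("+", "-")))
    stop("unknown strand '", setdiff(strand, c("+", "-"))[1], "' in ", path)
  s <- as.integer(f[exon, 4]); e <- as.integer(f[exon, 5])
  if (any(is.na(s) | is.na(e) | e < s))
    stop("bad exon coordinates in ", path)
  gid <- unname(mrna_parent[ex_parent])
  ord <- order(gid, ex_parent, s)
  gr <- GRanges(f[exon, 1][ord], IRanges(s[ord], e[ord]),
                strand = strand[ord],
                gene_id = gid[ord], transcript_id = ex_parent[ord],
                exon_rank = integer(length(ord)))
  rk <- unlist(lapply(split(seq_along(gr), mcols(gr)$transcript_id),
                      seq_along), use.names = FALSE)
  mcols(gr)$exon_rank[order(mcols(gr)$transcript_id,
                            start(gr))] <- rk
  # exon_rank in transcription order (reverse for minus strand)
  neg <- as.character(strand(gr)) == "-"
  if (any(neg)) {
    for (tx in unique(mcols(gr)$transcript_id[neg])) {
      ii <- which(mcols(gr)$transcript_id == tx)
      mcols(gr)$exon_rank[ii] <- rev(seq_along(ii))
    }
  }
  GeneModelSet(gr)
}

#' Write transcript models to GFF3
#'
#' Emits `gene`, `mRNA` and `exon` features (1-based inclusive).  The writer
#' is round-trip safe: [readGeneModelsGFF3] on the output reproduces the
#' coordinates exactly.  Exons are always written in ascending genomic order,
#' for minus-strand transcripts too.
#'
#' @param models a `GeneModelSet`
#' @param path output path
#' @param source value of the GFF3 source column
#' @return `path`, invisibly
#' @export
writeGeneModelsGFF3 <- function(models, path, source = "IsoScan") {
  ex <- modelExons(models)
  txs <- split(seq_along(ex), mcols(ex)$transcript_id)
  if (length(ex) && any(lengths(txs) == 0L))
    stop("transcript without exons")
  lines <- character(0)
  gsp <- geneSpans(models)
  dt <- data.table(gid = mcols(gsp)$gene_id,
                   contig = as.character(seqnames(gsp)),
                   s = start(gsp), e = end(gsp),
                   strand = as.character(strand(gsp)))
  setorder(dt, contig, s)
  for (i in seq_len(nrow(dt))) {
    g <- dt$gid[i]
    lines <- c(lines, sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              dt$contig[i], source, dt$s[i], dt$e[i],
                              dt$strand[i], g))
    gi <- which(mcols(ex)$gene_id == g)
    for (tx in unique(mcols(ex)$transcript_id[gi])) {
      ti <- gi[mcols(ex)$transcript_id[gi] == tx]
      ti <- ti[order(start(ex)[ti])]
      lines <- c(lines, sprintf(
        "%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        dt$contig[i], source, min(start(ex)[ti]), max(end(ex)[ti]),
        dt$strand[i], tx, g))
      lines <- c(lines, sprintf(
        "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
        dt$contig[i], source, start(ex)[ti], end(ex)[ti],
        as.character(strand(ex))[ti], tx))
    }
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## PSL
## ---------------------------------------------------------------------------

#' Read spliced alignments from a PSL file
#'
#' Parses the 21-column PSL dialect into a [SplicedAlignments] object.
#' Coverage and identity are recomputed from the match/mismatch/insert
#' fields rather than trusted, so alignments are scored identically
#' regardless of producer.  PSL 0-based half-open coordinates are converted
#' to the internal 1-based closed convention; minus-strand query coordinates
#' are flipped to forward-read coordinates.
#'
#' @param path path to a PSL file (no header expected; a `psLayout` header is
#'   skipped if present)
#' @return a `SplicedAlignments`
#' @export
readPslAlignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- grep("^[0-9]", lines, value = TRUE)   # skip psLayout header block
  if (!length(lines)) return(SplicedAlignments())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 21L))
    stop("malformed PSL (need 21 columns): ", path)
  rows <- vector("list", length(f))
  for (i in seq_along(f)) {
    v <- f[[i]]
    matches <- as.integer(v[1]); mism <- as.integer(v[2])
    qnum <- as.integer(v[5]); qbase <- as.integer(v[6])
    tnum <- as.integer(v[7]); tbase <- as.integer(v[8])
    strand <- v[9]; qname <- v[10]; qsize <- as.integer(v[11])
    tname <- v[14]
    bs <- as.integer(strsplit(v[19], ",")[[1]])
    qs <- as.integer(strsplit(v[20], ",")[[1]])
    ts <- as.integer(strsplit(v[21], ",")[[1]])
    bc <- as.integer(v[18])
    if (length(bs) != bc || length(qs) != bc || length(ts) != bc)
      stop("inconsistent blockSizes/qStarts/tStarts at PSL line ", i)
    ## PSL convention kept internally too: for "-" alignments the read
    ## coordinates are on the reverse-complemented query, so blocks ascend
    ## on both axes
    qstart <- qs + 1L
    blocks <- cbind(qstart = qstart, qend = qstart + bs - 1L,
                    tstart = ts + 1L, tend = ts + bs)
    blocks <- blocks[order(blocks[, "tstart"]), , drop = FALSE]
    # genomic gaps below min_intron were counted as tBaseInsert by the writer
    indels <- qbase + tbase
    aligned <- sum(bs)
    cov <- 100 * aligned / qsize
    ident <- 100 * matches / (matches + mism + indels)
    rows[[i]] <- data.frame(read_id = qname, contig = tname, strand = strand,
                            read_length = qsize, matches = matches,
                            mismatches = mism, indels = indels,
                            coverage = cov, identity = ident,
                            score = cov * ident / 100)
    rows[[i]]$blocks <- list(blocks)
  }
  SplicedAlignments(do.call(rbind, rows))
}

#' Write spliced alignments to PSL
#'
#' Inverse of [readPslAlignments]; genomic gaps >= `min_intron` are treated
#' as introns (not counted as tBaseInsert), smaller ones as insertions.
#'
#' @param aln a `SplicedAlignments`
#' @param path output path
#' @param min_intron smallest genomic gap regarded as an intron
#' @return `path`, invisibly
#' @export
writePslAlignments <- function(aln, path, min_intron = 40L) {
  tb <- alignmentTable(aln)
  lines <- character(nrow(tb))
  for (i in seq_len(nrow(tb))) {
    b <- tb$blocks[[i]]
    bs <- b[, 2] - b[, 1] + 1L
    qgaps <- if (nrow(b) > 1) b[-1, 1] - b[-nrow(b), 2] - 1L else integer(0)
    tgaps <- if (nrow(b) > 1) b[-1, 3] - b[-nrow(b), 4] - 1L else integer(0)
    tg_ins <- tgaps[tgaps < min_intron]
    qsize <- tb$read_length[i]
    strand <- tb$strand[i]
    qs <- b[, 1] - 1L
    lines[i] <- paste(
      tb$matches[i], tb$mismatches[i], 0L, 0L,
      sum(qgaps > 0), sum(qgaps), sum(tg_ins > 0), sum(tg_ins),
      strand, tb$read_id[i], qsize, min(b[, 1]) - 1L, max(b[, 2]),
      tb$contig[i], 0L, min(b[, 3]) - 1L, max(b[, 4]),
      nrow(b), paste0(paste(bs, collapse = ","), ","),
      paste0(paste(qs, collapse = ","), ","),
      paste0(paste(b[, 3] - 1L, collapse = ","), ","),
      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Junction BED6
## ---------------------------------------------------------------------------

#' Read splice junctions from BED6
#'
#' Columns: chrom, donor-1 (0-based), acceptor, name, support_count, strand.
#' `donor` is the first and `acceptor` the last intronic base (1-based,
#' forward genome coordinates).
#'
#' @param path BED6 path
#' @return data.frame with `contig, donor, acceptor, strand, support_count`
#' @export
readJunctionsBED <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("contig", "start0", "end", "name",
                                "support_count", "strand"),
                  colClasses = c("character", "integer", "integer",
                                 "character", "integer", "character"))
  data.frame(contig = x$contig, donor = x$start0 + 1L, acceptor = x$end,
             strand = x$strand, support_count = x$support_count,
             stringsAsFactors = FALSE)
}

#' Write splice junctions to BED6
#' @param junctions data.frame with `contig, donor, acceptor, strand,
#'   support_count`
#' @param path output path
#' @return `path`, invisibly
#' @export
writeJunctionsBED <- function(junctions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   junctions$contig, junctions$donor - 1L,
                   junctions$acceptor,
                   sprintf("J%06d", seq_len(nrow(junctions))),
                   junctions$support_count, junctions$strand)
  writeLines(lines, path)
  invisible(path)
}
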