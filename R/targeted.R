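## Targeted gene-family transcript search: similarity search of the FLNC set
## against family query sequences, ORF completeness / premature-stop
## detection, and non-redundant transcript reporting.  Designed for
## storage-protein (gluten) gene families: many highly similar single-exon
## homoeologs and paralogs.

.aln_cov_id <- function(read, target) {
  al <- banded_global_cpp(read, target,
                          max(60L, abs(nchar(read) - nchar(target)) + 80L))
  cov <- 100 * (al$nmatch + al$nmismatch) / nchar(read)
  ident <- 100 * al$nmatch / (al$nmatch + al$nmismatch + al$nins + al$ndel)
  c(coverage = cov, identity = ident, score = cov * ident / 100)
}

#' Search reads against gene-family query sequences
#'
#' Local (k-mer-prefiltered, banded gapped) alignment of every read against
#' every family query.  Hits passing the identity and query-coverage
#' thresholds are kept; each read is assigned to its best family by score
#' (ties broken by query id).
#'
#' @param reads named `DNAStringSet` of (corrected) FLNC reads
#' @param queries named `DNAStringSet` of family query sequences
#' @param families named character vector query id -> family label; default:
#'   each query is its own family
#' @param min_identity,min_query_coverage thresholds in percent
#' @return `data.frame` of hits: read, query, family, coverage, identity,
#'   score
#' @export
searchFamily <- function(reads, queries, families = NULL,
                         min_identity = 80, min_query_coverage = 80) {
  if (!length(queries)) stop("empty query set")
  if (is.null(families))
    families <- setNames(names(queries), names(queries))
  qs <- as.character(queries)
  rows <- list()
  for (ri in seq_along(reads)) {
    r <- as.character(reads[[ri]])
    best <- NULL
    for (qi in seq_along(qs)) {
      if (kmer_overlap_cpp(r, qs[qi], 12L) < 20L) next
      al <- banded_global_cpp(r, qs[qi],
                              max(60L, abs(nchar(r) - nchar(qs[qi])) + 80L))
      qcov <- 100 * (al$nmatch + al$nmismatch) / nchar(qs[qi])
      ident <- 100 * al$nmatch /
        (al$nmatch + al$nmismatch + al$nins + al$ndel)
      if (ident < min_identity || qcov < min_query_coverage) next
      sc <- qcov * ident / 100
      if (is.null(best) || sc > best$sc ||
          (sc == best$sc && names(qs)[qi] < best$query))
        best <- list(query = names(queries)[qi], sc = sc, cov = qcov,
                     id = ident)
    }
    if (!is.null(best))
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = names(reads)[ri], query_id = best$query,
        family = unname(families[best$query]), coverage = best$cov,
        identity = best$id, score = best$sc, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(read_id = character(0), query_id = character(0),
                      family = character(0), coverage = numeric(0),
                      identity = numeric(0), score = numeric(0)))
  do.call(rbind, rows)
}

#' ORF status of a read relative to a family query
#'
#' Locates the position homologous to the query's start codon via global
#' alignment, translates in that frame and compares the first in-frame stop
#' with the homologous position of the query's stop: COMPLETE_INTACT when it
#' falls within `stop_tolerance` codons of it, COMPLETE_DISRUPTED when an
#' earlier in-frame stop exists (the premature-stop codon index is
#' reported), PARTIAL when the start or stop region is missing from the
#' read.
#'
#' @param read character or `DNAString`: oriented (sense) read sequence
#' @param query character or `DNAString`: family query with a clean ORF
#' @param stop_tolerance codons of slack at the ORF end
#' @return list with `status`, `orf_start`, `orf_end` (read coordinates) and
#'   `premature_stop_pos` (codon index, `NA` unless disrupted)
#' @export
checkOrf <- function(read, query, stop_tolerance = 2L) {
  r <- as.character(read); q <- as.character(query)
  qorf <- .longest_orf(q)
  if (is.null(qorf)) stop("query has no detectable ORF")
  al <- banded_global_cpp(q, r, max(60L, abs(nchar(q) - nchar(r)) + 80L))
  ## map query positions to read positions through the cigar; remember which
  ## query positions were actual matches so the start mapping can be
  ## required to sit in locally anchored (not stray) alignment
  ops <- strsplit(al$ops, "")[[1]]
  qp <- 0L; rp <- 0L
  q2r <- integer(nchar(q))
  qmatch <- logical(nchar(q))
  for (op in ops) {
    if (op %in% c("=", "X")) { qp <- qp + 1L; rp <- rp + 1L; q2r[qp] <- rp
                               qmatch[qp] <- op == "=" }
    else if (op == "D") { qp <- qp + 1L; q2r[qp] <- NA_integer_ }
    else rp <- rp + 1L
  }
  ## ambiguous-base guard
  if (mean(strsplit(r, "")[[1]] %in% c("A", "C", "G", "T")) < 0.9) {
    warning("read largely untranslatable")
    return(list(status = "PARTIAL", orf_start = NA_integer_,
                orf_end = NA_integer_, premature_stop_pos = NA_integer_))
  }
  r_start <- q2r[qorf[1]]
  r_stop_end <- q2r[qorf[2]]
  ## the start must sit inside well-anchored alignment: a truncated read
  ## forces the global alignment to scatter the missing region as stray
  ## one-base matches, which this context check rejects
  win <- max(1L, qorf[1] - 10L):min(nchar(q), qorf[1] + 20L)
  anchored <- mean(qmatch[win]) >= 0.7
  if (!anchored || is.na(r_start) || r_start < 1L ||
      substr(r, r_start, r_start + 2L) != "ATG" || is.na(r_stop_end))
    return(list(status = "PARTIAL", orf_start = NA_integer_,
                orf_end = NA_integer_, premature_stop_pos = NA_integer_))
  n_codons_q <- (qorf[2] - qorf[1] + 1L) %/% 3L
  ## translate from the read start codon
  ix <- seq(r_start, nchar(r) - 2L, by = 3L)
  cod <- substring(r, ix, ix + 2L)
  stop_i <- which(cod %in% c("TAA", "TAG", "TGA"))
  if (!length(stop_i))
    return(list(status = "PARTIAL", orf_start = r_start,
                orf_end = NA_integer_, premature_stop_pos = NA_integer_))
  first_stop <- stop_i[1]
  if (abs(first_stop - n_codons_q) <= stop_tolerance)
    return(list(status = "COMPLETE_INTACT", orf_start = r_start,
                orf_end = ix[first_stop] + 2L,
                premature_stop_pos = NA_integer_))
  if (first_stop < n_codons_q - stop_tolerance)
    return(list(status = "COMPLETE_DISRUPTED", orf_start = r_start,
                orf_end = ix[first_stop] + 2L,
                premature_stop_pos = first_stop))
  list(status = "PARTIAL", orf_start = r_start, orf_end = NA_integer_,
       premature_stop_pos = NA_integer_)
}

#' Non-redundant family transcripts
#'
#' Reads with a complete ORF are clustered at `min_cluster_identity` over
#' their full length (sequence clustering -- these families are single-exon,
#' so junction chains do not apply); each cluster yields one representative
#' transcript.  Cluster ORF status and premature-stop position are decided
#' by majority over the member reads.
#'
#' @param hits result of [searchFamily]
#' @param reads named `DNAStringSet`
#' @param queries named `DNAStringSet` of family queries
#' @param min_cluster_identity clustering threshold in percent; chosen to
#'   separate paralogs (>= 3 percent diverged) while absorbing residual read
#'   error (about 1 percent)
#' @return list with `clusters` (one row per non-redundant transcript),
#'   `reads` (per-read ORF calls) and `summary` (per family: positive reads,
#'   complete reads, unique transcripts, intact/disrupted counts; plus
#'   overall totals and the complete-ORF percentage, 1 decimal)
#' @export
dedupeFamilyTranscripts <- function(hits, reads, queries,
                                    min_cluster_identity = 99) {
  if (!nrow(hits))
    return(list(clusters = data.frame(), reads = data.frame(),
                summary = list()))
  orf <- lapply(seq_len(nrow(hits)), function(i)
    checkOrf(reads[[hits$read_id[i]]], queries[[hits$query_id[i]]]))
  hits$orf_status <- vapply(orf, `[[`, "", "status")
  hits$premature_stop_pos <- vapply(orf, function(x)
    as.integer(x$premature_stop_pos), 0L)
  comp <- hits[startsWith(hits$orf_status, "COMPLETE"), , drop = FALSE]
  clusters <- list()
  if (nrow(comp)) {
    for (fam in unique(comp$family)) {
      cc <- comp[comp$family == fam, , drop = FALSE]
      ## two-stage clustering.  Stage 1: greedy best-cluster assignment at a
      ## read-to-read threshold -- both sequences carry the residual error
      ## budget, so the pairwise bound is twice as loose as the allele-level
      ## one.  Stage 2: polish each representative by majority consensus of
      ## its members and reassign every read against the polished alleles at
      ## the allele-level threshold.
      pair_thr <- 100 - 2 * (100 - min_cluster_identity) - 0.5
      reps <- list()
      assign <- integer(nrow(cc))
      for (i in seq_len(nrow(cc))) {
        r <- as.character(reads[[cc$read_id[i]]])
        best_ci <- 0L; best_id <- -1
        for (ci in seq_along(reps)) {
          m <- .aln_cov_id(r, reps[[ci]])
          if (m["coverage"] >= 95 && m["identity"] > best_id) {
            best_id <- m["identity"]; best_ci <- ci
          }
        }
        if (best_ci > 0L && best_id >= pair_thr) assign[i] <- best_ci
        else { reps[[length(reps) + 1L]] <- r
               assign[i] <- length(reps) }
      }
      ## polish representatives of substantial clusters by majority
      ## consensus -- their residual error then drops far below the allele
      ## divergence
      sizes <- tabulate(assign, nbins = length(reps))
      polished <- which(sizes >= 3L)
      if (!length(polished)) polished <- which(sizes >= 1L)
      for (ci in polished) {
        mem_reads <- as.character(reads[cc$read_id[assign == ci]])
        if (length(mem_reads) >= 3L) {
          pickn <- head(mem_reads, 9L)
          ref <- pickn[which.max(nchar(pickn))]
          reps[[ci]] <- consensus_cpp(ref, setdiff(pickn, ref),
                                      0.08)$consensus
        }
      }
      ## merge polished clusters whose representatives meet the allele-level
      ## threshold (noise can seed several clusters of one allele)
      if (length(polished) > 1L) {
        ord_p <- polished[order(-sizes[polished])]
        kept <- ord_p[1]
        for (ci in ord_p[-1]) {
          merged <- FALSE
          for (cj in kept) {
            m <- .aln_cov_id(reps[[ci]], reps[[cj]])
            if (m["coverage"] >= 95 &&
                m["identity"] >= min_cluster_identity) {
              merged <- TRUE; break
            }
          }
          if (!merged) kept <- c(kept, ci)
        }
        polished <- kept
      }
      ## reassign every read to its best polished representative; clusters
      ## below the polish threshold dissolve entirely (minimum support)
      for (i in seq_len(nrow(cc))) {
        r <- as.character(reads[[cc$read_id[i]]])
        best_ci <- 0L; best_id <- -1
        for (ci in polished) {
          m <- .aln_cov_id(r, reps[[ci]])
          if (m["coverage"] >= 95 && m["identity"] > best_id) {
            best_id <- m["identity"]; best_ci <- ci
          }
        }
        if (best_ci > 0L) assign[i] <- best_ci
      }
      keep_ci <- sort(unique(assign))
      for (ci in keep_ci) {
        mem <- cc[assign == ci, , drop = FALSE]
        ## ORF status of the non-redundant transcript is judged on the
        ## polished consensus: residual per-read indels shift reading
        ## frames and would otherwise flag noise as disruption
        rep_orf <- checkOrf(reps[[ci]],
                            queries[[mem$query_id[1]]])
        status <- rep_orf$status
        stop_pos <- rep_orf$premature_stop_pos
        clusters[[length(clusters) + 1L]] <- data.frame(
          family = fam, cluster = sprintf("%s.c%02d", fam, ci),
          n_reads = nrow(mem), representative_read = mem$read_id[1],
          orf_status = status, premature_stop_pos = stop_pos,
          stringsAsFactors = FALSE)
      }
    }
  }
  cl <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(family = character(0), cluster = character(0),
               n_reads = integer(0), representative_read = character(0),
               orf_status = character(0), premature_stop_pos = integer(0))
  fam_sum <- lapply(unique(hits$family), function(fam) {
    hh <- hits[hits$family == fam, , drop = FALSE]
    ccl <- cl[cl$family == fam, , drop = FALSE]
    data.frame(family = fam, n_positive_reads = nrow(hh),
               n_complete_reads = sum(startsWith(hh$orf_status, "COMPLETE")),
               n_unique_transcripts = nrow(ccl),
               n_intact = sum(ccl$orf_status == "COMPLETE_INTACT"),
               n_disrupted = sum(ccl$orf_status == "COMPLETE_DISRUPTED"),
               stringsAsFactors = FALSE)
  })
  fam_sum <- do.call(rbind, fam_sum)
  totals <- list(
    n_positive_reads = nrow(hits),
    n_complete_reads = sum(startsWith(hits$orf_status, "COMPLETE")),
    n_unique_transcripts = nrow(cl),
    complete_orf_percent = round(
      100 * sum(startsWith(hits$orf_status, "COMPLETE")) / nrow(hits), 1))
  list(clusters = cl, reads = hits,
       summary = list(per_family = fam_sum, totals = totals))
}
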