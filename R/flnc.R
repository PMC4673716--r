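## From continuous long reads to corrected FLNC reads: subread splitting,
## circular-consensus calling, primer/poly(A)/chimera classification and
## hybrid correction with short reads.

#' FLNC processing configuration
#'
#' Thresholds of the CLR -> FLNC path.  `mini_length`/`read_score` filter
#' subreads; `min_complete_passes` separates type I (consensus) from type II
#' (single-pass) reads; `min_predicted_accuracy` gates consensus reads;
#' `min_polya` is the minimum poly(A) run (allowing `polya_impurity` non-A);
#' `primer_max_mismatch_frac` is the edit-distance budget for primer and
#' adapter matching; `correction_min_depth` the pileup depth required to
#' alter a base during short-read correction.
#'
#' @param mini_length minimum subread length
#' @param read_score minimum read-score proxy
#' @param min_complete_passes subreads needed for a consensus read
#' @param min_predicted_accuracy minimum predicted consensus accuracy
#' @param min_polya minimum poly(A) run length
#' @param polya_impurity tolerated non-A fraction inside the poly(A) run
#' @param primer_max_mismatch_frac edit budget as a fraction of primer length
#' @param adapter_max_mismatch_frac edit budget for the hairpin adapter; more
#'   permissive than the primer budget because a missed adapter merges two
#'   passes (costly) while a spurious split is almost free
#' @param correction_min_depth minimum pileup depth for correction
#' @return a validated list of class `FlncConfig`
#' @export
flncConfig <- function(mini_length = 50L, read_score = 0.75,
                       min_complete_passes = 2L,
                       min_predicted_accuracy = 0,
                       min_polya = 20L, polya_impurity = 0.1,
                       primer_max_mismatch_frac = 0.2,
                       adapter_max_mismatch_frac = 0.3,
                       correction_min_depth = 3L) {
  cfg <- list(mini_length = as.integer(mini_length), read_score = read_score,
              min_complete_passes = as.integer(min_complete_passes),
              min_predicted_accuracy = min_predicted_accuracy,
              min_polya = as.integer(min_polya),
              polya_impurity = polya_impurity,
              primer_max_mismatch_frac = primer_max_mismatch_frac,
              adapter_max_mismatch_frac = adapter_max_mismatch_frac,
              correction_min_depth = as.integer(correction_min_depth))
  stopifnot(cfg$mini_length > 0L, cfg$read_score >= 0, cfg$read_score <= 1,
            cfg$min_complete_passes >= 1L,
            cfg$min_predicted_accuracy >= 0, cfg$min_predicted_accuracy <= 1,
            cfg$min_polya >= 1L, cfg$polya_impurity >= 0,
            cfg$polya_impurity < 0.5,
            cfg$primer_max_mismatch_frac >= 0,
            cfg$primer_max_mismatch_frac < 0.5,
            cfg$adapter_max_mismatch_frac >= 0,
            cfg$adapter_max_mismatch_frac < 0.5,
            cfg$correction_min_depth >= 1L)
  class(cfg) <- "FlncConfig"
  cfg
}

#' Split a continuous long read into oriented subreads
#'
#' Cuts the CLR at every approximate occurrence of the hairpin adapter
#' (edit distance up to `primer_max_mismatch_frac` of the adapter length),
#' drops fragments shorter than `mini_length` or from reads below the
#' `read_score` threshold, and reverse-complements antisense passes onto a
#' common orientation (decided by shared k-mer content against the first
#' fragment).
#'
#' @param clr character or `DNAString`: the raw read sequence
#' @param adapter adapter sequence
#' @param config an [flncConfig]
#' @param read_score read-level quality proxy in \\[0,1]
#' @return character vector of subread sequences (possibly empty)
#' @export
splitSubreads <- function(clr, adapter, config = flncConfig(),
                          read_score = 1.0) {
  seq <- as.character(clr)
  if (read_score < config$read_score) return(character(0))
  max_ed <- ceiling(config$adapter_max_mismatch_frac * nchar(adapter))
  hits <- find_pattern_hits_cpp(adapter, seq, max_ed)
  bounds <- c(0L, as.integer(t(cbind(hits$start - 1L, hits$end))),
              nchar(seq))
  frs <- character(0)
  for (i in seq(1L, length(bounds) - 1L, by = 2L)) {
    s <- bounds[i] + 1L; e <- bounds[i + 1L]
    if (e - s + 1L >= config$mini_length)
      frs <- c(frs, substr(seq, s, e))
  }
  if (length(frs) <= 1L) return(frs)
  # orient all fragments like the first
  ref <- frs[1]
  for (i in 2:length(frs)) {
    rc <- .revcomp_chr(frs[i])
    if (kmer_overlap_cpp(rc, ref, 12L) > kmer_overlap_cpp(frs[i], ref, 12L))
      frs[i] <- rc
  }
  frs
}

#' Build a circular consensus read from subreads
#'
#' With `>= min_complete_passes` subreads, all are pairwise aligned to the
#' longest one and a per-column majority vote (ties keep the longest
#' subread's base) yields the consensus; the predicted accuracy is the mean
#' agreement of the subreads with the consensus.  A single subread passes
#' through as a type II read.
#'
#' @param subreads character vector of oriented subread sequences
#' @param config an [flncConfig]
#' @return list with `sequence`, `n_passes`, `predicted_accuracy`, `type`
#'   ("I"/"II"); or `NULL` when rejected (no subreads or accuracy below
#'   threshold)
#' @export
buildCcs <- function(subreads, config = flncConfig()) {
  if (!length(subreads)) return(NULL)
  if (length(subreads) < config$min_complete_passes) {
    if (length(subreads) == 1L)
      return(list(sequence = subreads[1], n_passes = 1L,
                  predicted_accuracy = NA_real_, type = "II"))
    # fewer subreads than required for a consensus, more than one: keep the
    # longest as a single-pass read
    return(list(sequence = subreads[which.max(nchar(subreads))],
                n_passes = 1L, predicted_accuracy = NA_real_, type = "II"))
  }
  ## an undetected adapter merges two passes into a double-length fragment;
  ## exclude such fragments and take the longest typical one as reference
  if (length(subreads) >= 3L) {
    med <- stats::median(nchar(subreads))
    ok <- nchar(subreads) <= 1.6 * med
    if (sum(ok) >= config$min_complete_passes) subreads <- subreads[ok]
  }
  ord <- order(nchar(subreads), decreasing = TRUE)
  ref <- subreads[ord[1]]
  others <- subreads[ord[-1]]
  if (all(others == ref)) {
    cons <- ref; acc <- 1.0
  } else {
    cc <- consensus_cpp(ref, others, 0.08)
    cons <- cc$consensus
    acc <- mean(cc$agreement)
  }
  if (!is.na(acc) && acc < config$min_predicted_accuracy) return(NULL)
  list(sequence = cons, n_passes = length(subreads),
       predicted_accuracy = acc, type = "I")
}

.best_hit <- function(pattern, text, max_ed) {
  h <- find_pattern_hits_cpp(pattern, text, max_ed)
  if (!nrow(h)) return(NULL)
  h[which.min(h$ed), , drop = FALSE]
}

#' Classify a consensus read as FLNC or reject it
#'
#' A read is full-length non-chimeric when it carries the 5' primer at its
#' start, the 3' primer at its end preceded by a distinct poly(A) tail of at
#' least `min_polya` bases, and no additional primer occurrence in its
#' interior.  Orientation is fixed so the 5' primer leads; primers and
#' poly(A) are trimmed from the returned sequence.
#'
#' @param consensus list from [buildCcs] (or a bare character sequence)
#' @param primers named vector with `p5` and `p3` (see [isoPrimers])
#' @param config an [flncConfig]
#' @return list with `status` ("flnc", "no_5p", "no_3p", "no_polya",
#'   "chimeric") and, for FLNC, `sequence`, `polya_len`, `source_type`,
#'   `n_passes`
#' @export
classifyFlnc <- function(consensus, primers = isoPrimers(),
                         config = flncConfig()) {
  if (is.character(consensus))
    consensus <- list(sequence = consensus, n_passes = 1L,
                      predicted_accuracy = NA_real_, type = "II")
  seq <- consensus$sequence
  p5 <- unname(primers["p5"])
  p3rc <- .revcomp_chr(unname(primers["p3"]))
  ed5 <- ceiling(config$primer_max_mismatch_frac * nchar(p5))
  ed3 <- ceiling(config$primer_max_mismatch_frac * nchar(p3rc))
  win <- 140L
  score_orient <- function(s) {
    n <- nchar(s)
    head5 <- substr(s, 1L, min(n, win))
    tail3 <- substr(s, max(1L, n - win + 1L), n)
    h5 <- .best_hit(p5, head5, ed5)
    h3 <- .best_hit(p3rc, tail3, ed3)
    list(h5 = h5, h3 = h3,
         found = !is.null(h5) + !is.null(h3),
         ed = (if (is.null(h5)) ed5 + 1L else h5$ed) +
              (if (is.null(h3)) ed3 + 1L else h3$ed))
  }
  fwd <- score_orient(seq)
  rcseq <- .revcomp_chr(seq)
  rev <- score_orient(rcseq)
  use_rev <- rev$found > fwd$found ||
    (rev$found == fwd$found && rev$ed < fwd$ed)
  if (use_rev) { seq <- rcseq; o <- rev } else o <- fwd
  if (is.null(o$h5)) return(list(status = "no_5p"))
  if (is.null(o$h3)) return(list(status = "no_3p"))
  n <- nchar(seq)
  ins_start <- o$h5$end + 1L
  p3_start <- max(1L, n - win + 1L) + o$h3$start - 1L
  ## poly(A) immediately upstream of the 3' primer (allow a few slop bases)
  best_run <- list(length = 0L, start = p3_start)
  for (e in p3_start - seq_len(min(14L, p3_start - 1L))) {
    run <- polya_run_cpp(seq, e, config$polya_impurity)
    if (run$length > best_run$length) best_run <- run
  }
  if (best_run$length < config$min_polya) return(list(status = "no_polya"))
  ins_end <- best_run$start - 1L
  if (ins_end <= ins_start) return(list(status = "no_polya"))
  ## interior primer scan (>= 50 nt away from either trim point)
  interior <- substr(seq, ins_start + 50L, ins_end - 50L)
  if (nchar(interior) >= nchar(p5)) {
    for (pat in c(p5, p3rc, .revcomp_chr(p5), unname(primers["p3"]))) {
      h <- find_pattern_hits_cpp(pat, interior,
                                 ceiling(config$primer_max_mismatch_frac *
                                           nchar(pat)))
      if (nrow(h)) return(list(status = "chimeric"))
    }
  }
  list(status = "flnc",
       sequence = substr(seq, ins_start, ins_end),
       polya_len = best_run$length,
       source_type = consensus$type,
       n_passes = consensus$n_passes,
       predicted_accuracy = consensus$predicted_accuracy)
}

#' Run the CLR -> FLNC stage over a read set
#'
#' @param clrs `DNAStringSet` of continuous long reads
#' @param scores optional named numeric vector of read scores (default 1)
#' @param primers named vector with `p5`, `p3`, `adapter`
#' @param config an [flncConfig]
#' @return list with `flnc` (an [FlncSet]), `stats` (stage counts) and
#'   `rejections` (per-read status for non-FLNC reads)
#' @export
runFlnc <- function(clrs, scores = NULL, primers = isoPrimers(),
                    config = flncConfig()) {
  ids <- names(clrs)
  if (is.null(scores)) scores <- setNames(rep(1.0, length(clrs)), ids)
  seqs <- as.character(clrs)
  n_sub <- 0L; n_ccs <- 0L
  keep_seq <- character(0); keep_info <- list()
  rej <- character(0); rej_id <- character(0)
  for (i in seq_along(seqs)) {
    sr <- splitSubreads(seqs[i], primers["adapter"], config,
                        read_score = scores[ids[i]])
    n_sub <- n_sub + length(sr)
    cc <- buildCcs(sr, config)
    if (is.null(cc)) {
      rej <- c(rej, "filtered"); rej_id <- c(rej_id, ids[i]); next
    }
    if (cc$type == "I") n_ccs <- n_ccs + 1L
    cl <- classifyFlnc(cc, primers, config)
    if (cl$status != "flnc") {
      rej <- c(rej, cl$status); rej_id <- c(rej_id, ids[i]); next
    }
    keep_seq <- c(keep_seq, cl$sequence)
    keep_info[[length(keep_info) + 1L]] <- data.frame(
      id = ids[i], polya_len = cl$polya_len, had_5p_primer = TRUE,
      had_3p_primer = TRUE, source_type = cl$source_type,
      n_passes = cl$n_passes, corrected = FALSE, stringsAsFactors = FALSE)
  }
  info <- if (length(keep_info)) do.call(rbind, keep_info) else NULL
  fl <- FlncSet(DNAStringSet(keep_seq), info)
  stats <- list(n_clr = length(seqs), n_subreads = n_sub, n_ccs = n_ccs,
                n_flnc = length(fl),
                n_flnc_type_I = sum(flncInfo(fl)$source_type == "I"),
                n_flnc_type_II = sum(flncInfo(fl)$source_type == "II"),
                rejections = table(factor(rej, levels = c(
                  "filtered", "no_5p", "no_3p", "no_polya", "chimeric"))))
  list(flnc = fl, stats = stats,
       rejections = data.frame(read_id = rej_id, status = rej,
                               stringsAsFactors = FALSE))
}

#' Correct FLNC reads with short-read pileups
#'
#' Short reads are anchored on each FLNC read by exact 15-mer seeds, banded
#' aligned, and piled up; positions with depth >= `correction_min_depth`
#' are replaced by the pileup majority (substitutions and indels up to 3
#' nt).  Reads without coverage pass through unchanged with
#' `corrected = FALSE`.
#'
#' @param flnc an [FlncSet]
#' @param short_reads a `DNAStringSet` (or list of them, pooled)
#' @param config an [flncConfig]
#' @param templates optional named `DNAStringSet` of true templates (one per
#'   read id) for the identity report
#' @return list with `flnc` (corrected [FlncSet]) and `report` (mean
#'   identity to template before/after, `NA` without templates)
#' @export
correctWithShortReads <- function(flnc, short_reads, config = flncConfig(),
                                  templates = NULL) {
  if (is.list(short_reads) && !is(short_reads, "DNAStringSet"))
    short_reads <- do.call(c, unname(short_reads))
  k <- 15L
  fseqs <- as.character(flncSequences(flnc))
  sseqs <- as.character(short_reads)
  ## index FLNC positions, query sampled short-read k-mers; short reads are
  ## processed in chunks to bound the size of the seed join
  ft <- kmer_table_cpp(fseqs, k, 1L)
  fidx <- data.table(kmer = ft$kmer, fl = ft$id, fp = ft$pos)
  setkey(fidx, kmer)
  chunk <- 150000L
  starts_at <- seq(1L, max(1L, length(sseqs)), by = chunk)
  bests <- vector("list", length(starts_at))
  for (ci in seq_along(starts_at)) {
    lo <- starts_at[ci]; hi <- min(length(sseqs), lo + chunk - 1L)
    st <- kmer_table_cpp(sseqs[lo:hi], k, 5L)
    sidx <- data.table(kmer = st$kmer, sr = st$id + lo - 1L, sp = st$pos)
    hits <- if (nrow(sidx)) fidx[sidx, on = "kmer", nomatch = NULL,
                                 allow.cartesian = TRUE] else data.table()
    if (!nrow(hits)) next
    hits[, diag := fp - sp + 1L]
    # modal diagonal per (short read, flnc), >= 2 agreeing seeds
    hits[, dgrp := round(diag / 10)]
    cand <- hits[, .N, by = .(fl, sr, dgrp)][N >= 2L]
    bests[[ci]] <- hits[cand, on = .(fl, sr, dgrp)][
      , .(start = as.integer(round(stats::median(diag)))), by = .(fl, sr)]
    rm(hits, sidx, cand)
  }
  best <- rbindlist(bests)
  rm(bests)
  out_seqs <- fseqs
  corrected <- logical(length(fseqs))
  if (nrow(best)) {
    setorder(best, fl, sr)
    ## cap the pileup at ~25x coverage per target: majority voting gains
    ## nothing beyond that and the alignment cost is linear in depth.
    ## Thin systematically across the candidate list -- a head-of-list cut
    ## would bias the pileup toward whichever library comes first.
    best[, rk := seq_len(.N), by = fl]
    best[, nfl := .N, by = fl]
    cap <- pmin(best$nfl, ceiling(nchar(fseqs[best$fl]) / 101 * 25))
    best <- best[rk %% pmax(1L, as.integer(best$nfl / cap)) == 0L |
                   best$nfl <= cap]
    res <- pileup_correct_multi_cpp(fseqs, sseqs, best$sr, best$fl,
                                    best$start, 12L,
                                    config$correction_min_depth, 1L)
    out_seqs <- as.character(res$corrected)
    corrected <- res$n_voting >= config$correction_min_depth
  }
  id_before <- id_after <- NA_real_
  if (!is.null(templates)) {
    ids <- flncInfo(flnc)$id
    tpl <- as.character(templates)
    mids <- intersect(ids, names(tpl))
    pid <- function(a, b) {
      band <- max(30L, ceiling(0.2 * max(nchar(a), nchar(b))))
      r <- banded_global_cpp(a, b, band)
      100 * r$nmatch / (r$nmatch + r$nmismatch + r$nins + r$ndel)
    }
    ix <- match(mids, ids)
    id_before <- mean(vapply(seq_along(mids), function(j)
      pid(fseqs[ix[j]], tpl[mids[j]]), 0))
    id_after <- mean(vapply(seq_along(mids), function(j)
      pid(out_seqs[ix[j]], tpl[mids[j]]), 0))
  }
  info <- flncInfo(flnc)
  info$corrected <- corrected
  list(flnc = FlncSet(DNAStringSet(setNames(out_seqs, info$id)), info),
       report = list(mean_identity_before = id_before,
                     mean_identity_after = id_after,
                     n_corrected = sum(corrected)))
}
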