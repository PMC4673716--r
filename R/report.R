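## Reporting layer: the published headline counts of the wheat grain
## full-length cDNA survey this pipeline follows, the derived-figure
## arithmetic (sums, differences, percentages exactly as printed), and the
## end-to-end pipeline driver with its additive consistency checks.

.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percentage formatted the way study reports print it
#'
#' Half-up rounding at reporting time only; internal values keep full
#' precision.
#'
#' @param numerator,denominator counts
#' @param digits decimals (study reports use 1 or 2)
#' @return numeric percentage rounded half-up, `NA` with a message when the
#'   denominator is zero
#' @export
derivePercentage <- function(numerator, denominator, digits = 1) {
  if (denominator == 0) {
    message("zero denominator: percentage omitted")
    return(NA_real_)
  }
  .round_half_up(100 * numerator / denominator, digits)
}

#' Headline counts of the published wheat grain full-length cDNA survey
#'
#' The printed counts of the hexaploid wheat (Chinese Spring draft genome,
#' Xiaoyan 81 grain) single-molecule full-length cDNA survey whose analysis
#' this package implements.  They are inputs to the reporting arithmetic:
#' [deriveSummary] recomputes every derived figure (totals, differences,
#' percentages) from these raw counts.
#'
#' @return nested list of printed counts
#' @export
wheatStudyCounts <- function() {
  list(
    clr_total = 526915,
    subreads_type_I = 1618400,
    ccs = 240312,
    flnc_type_I = 175375,
    flnc_type_II = 22334,
    identity_before_correction = 96.2,
    identity_after_correction = 98.3,
    orf = list(shared_loci = 1347, reads_at_shared_loci = 28599,
               reads_with_complete_orf = 21326),
    undetermined_direction = 10944,
    groups = c(G1 = 134204, G2 = 15352, G3 = 27014, G4 = 8669, G5 = 1526),
    junction_supported_percent = 96,
    motif_percent = c(`GT-AG` = 98.51, `GC-AG` = 1.29, `AT-AC` = 0.11,
                      other = 0.09),
    g2 = list(below_band = 303, one_best_per_subgenome = 554,
              multi_within_one = 6348, multi_across = 8147),
    g3 = list(two_contigs = 6102, complex = 20912, same_arm = 4219,
              contiguous_Dt = 90, contiguous_Au = 200),
    rescue = c(Au = 3076, Dt = 2150),
    hq = list(excluded = 42323, reads_extant = 83736, reads_novel = 8145,
              loci_extant = 13162, loci_novel = 3026,
              novel_regions = 3745, novel_with_other_models = 666,
              novel_without_models = 2360, novel_annotated = 2433,
              loci_gt100_reads = 49),
    transcripts = list(at_known_loci = 19023, confirming = 13177,
                       new_at_known = 5846, at_novel_loci = 3745,
                       new_len = c(min = 575, max = 4537, mean = 2433),
                       known_len = c(min = 671, max = 4636, mean = 2388)),
    spanning = list(n = 180, orf_aa = c(min = 80, max = 1307),
                    validated_bd = 66, validated_rice = 28),
    expression = list(
      expressed = c(S1 = 50650, S2 = 42444, S3 = 44547, S4 = 37369),
      covered = c(S1 = 11798, S2 = 9452, S3 = 10626, S4 = 8676),
      tx_detected = c(S1 = 17330, S2 = 13938, S3 = 15909, S4 = 12943),
      differential = 6030, single_isoform = 4783, multi_isoform = 1247),
    gluten = list(
      reads = c(`HMW-GS` = 574, `LMW-GS` = 139, `alpha-beta-gliadin` = 263,
                `gamma-gliadin` = 208, `omega-gliadin` = 27),
      transcripts = c(`HMW-GS` = 6, `LMW-GS` = 14,
                      `alpha-beta-gliadin` = 32, `gamma-gliadin` = 14,
                      `omega-gliadin` = 6),
      positive_reads = 1577, complete_reads = 1211)
  )
}

#' Derived figures from raw counts
#'
#' Recomputes every derived figure a study report prints from its raw
#' counts: totals by addition, exclusions by subtraction, and percentages by
#' [derivePercentage].  Also evaluates the additive identities that must
#' hold (`checks`).
#'
#' @param counts a counts list shaped like [wheatStudyCounts]
#' @return list with `derived` values and logical `checks`
#' @export
deriveSummary <- function(counts) {
  cs <- counts
  flnc_total <- cs$flnc_type_I + cs$flnc_type_II
  resolved <- flnc_total - cs$undetermined_direction
  hq_total <- cs$groups[["G1"]] - cs$hq$excluded
  loci_total <- cs$hq$loci_extant + cs$hq$loci_novel
  tx_total <- cs$transcripts$at_known_loci + cs$transcripts$at_novel_loci
  novel_tx <- cs$transcripts$new_at_known + cs$transcripts$at_novel_loci
  g2_retained <- sum(cs$groups[["G2"]]) - cs$g2$below_band
  derived <- list(
    flnc_total = flnc_total,
    direction_resolved = resolved,
    g1_percent_of_flnc = derivePercentage(cs$groups[["G1"]], flnc_total, 2),
    hq_total = hq_total,
    loci_total = loci_total,
    transcripts_total = tx_total,
    novel_transcripts = novel_tx,
    transcripts_confirming = cs$transcripts$at_known_loci -
      cs$transcripts$new_at_known,
    orf_complete_percent = derivePercentage(
      cs$orf$reads_with_complete_orf, cs$orf$reads_at_shared_loci, 1),
    novel_loci_annotated_percent = derivePercentage(
      cs$hq$novel_annotated, cs$hq$loci_novel, 1),
    mean_length_difference = cs$transcripts$new_len[["mean"]] -
      cs$transcripts$known_len[["mean"]],
    g2_retained = g2_retained,
    gluten_transcripts_total = sum(cs$gluten$transcripts),
    gluten_complete_percent = derivePercentage(
      cs$gluten$complete_reads, cs$gluten$positive_reads, 1),
    differential_genes = cs$expression$single_isoform +
      cs$expression$multi_isoform)
  checks <- c(
    hq_partition = hq_total ==
      cs$hq$reads_extant + cs$hq$reads_novel,
    groups_sum_to_resolved = sum(cs$groups) == resolved,
    g2_patterns_sum = cs$g2$one_best_per_subgenome +
      cs$g2$multi_within_one + cs$g2$multi_across == g2_retained,
    novel_loci_split = cs$hq$novel_with_other_models +
      cs$hq$novel_without_models == cs$hq$loci_novel,
    gluten_reads_sum = sum(cs$gluten$reads) == cs$gluten$complete_reads,
    differential_split = derived$differential_genes ==
      cs$expression$differential,
    motif_sums_to_100 = abs(sum(cs$motif_percent) - 100) < 0.05)
  list(derived = derived, checks = checks)
}

## ---------------------------------------------------------------------------
## pipeline driver
## ---------------------------------------------------------------------------

.stage_file <- function(outdir, stage) file.path(outdir,
                                                 paste0(stage, ".rds"))

.run_stage <- function(name, outdir, resume, fun) {
  f <- .stage_file(outdir, name)
  if (resume && file.exists(f)) {
    message("stage ", name, ": resumed from ", f)
    return(readRDS(f))
  }
  message("stage ", name, ": running")
  x <- fun()
  saveRDS(x, f)
  x
}

#' Run the full synthetic-study pipeline
#'
#' Executes the stages in order -- simulate, flnc (with short-read
#' correction), map, classify, annotate, isoforms, express -- writing each
#' stage's output under `outdir` before the next begins, so a failed run can
#' be resumed from the last completed stage.  Returns the stage outputs plus
#' a summary report whose additive identities are asserted.
#'
#' @param config a [simConfig]
#' @param outdir output directory (created if missing)
#' @param resume reuse stage outputs already present in `outdir`
#' @param correct run short-read error correction of the FLNC reads
#' @return list of class `IsoScanRun` with all stage outputs and `report`
#' @export
runPipeline <- function(config = simConfig(), outdir = tempfile("isoscan_"),
                        resume = FALSE, correct = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- .run_stage("simulate", outdir, resume, function() {
    s <- simulateGenome(config)
    list(sim = s, clr = simulateClrReads(config, s),
         short = simulateShortReads(config, s))
  })
  flnc <- .run_stage("flnc", outdir, resume, function() {
    fl <- runFlnc(sim$clr$reads, sim$clr$scores)
    if (correct) {
      co <- correctWithShortReads(fl$flnc, sim$short)
      fl$flnc <- co$flnc
      fl$correction <- co$report
    }
    fl
  })
  map <- .run_stage("map", outdir, resume, function() {
    gi <- genomeIndex(sim$sim$draftContigs)
    aln <- toySplicedAlign(flncSequences(flnc$flnc), gi)
    list(aln = aln)
  })
  classify <- .run_stage("classify", outdir, resume, function() {
    groups <- classifyReadGroups(map$aln, sim$sim$draftContigs,
                                 read_ids = flncInfo(flnc$flnc)$id)
    g2 <- g2PatternAnalysis(groups,
                            contigSubgenomeMap(names(sim$sim$draftContigs)))
    ## candidate transcript index for short-read evidence: draft models plus
    ## the distinct junction-chain transcripts observed among G1 reads
    tx_table <- .candidate_tx_table(groups, map$aln, sim$sim$draftModels)
    ev <- shortReadEvidence(sim$short, tx_table, sim$sim$draftContigs)
    best <- .best_per_read(map$aln)
    g1aln <- SplicedAlignments(
      best[best$read_id %in% groups$read_id[groups$group == "G1"], ,
           drop = FALSE])
    lj <- extractJunctions(g1aln, sim$sim$draftContigs)
    sj <- ev$junctions
    sj$strand <- NA_character_
    val <- .validate_no_strand(lj, sj)
    list(groups = groups, g2 = g2, evidence = ev, junction_validation = val,
         tx_table = tx_table)
  })
  annotate <- .run_stage("annotate", outdir, resume, function() {
    hq <- filterHighQuality(classify$groups, map$aln,
                            classify$evidence$junctions,
                            short_reads = do.call(c, unname(sim$short)),
                            genome = sim$sim$draftContigs)
    loci <- assignLoci(hq, sim$sim$draftModels)
    ## ortholog alignments of the G3 reads
    g3ids <- classify$groups$read_id[classify$groups$group == "G3"]
    ort_genome <- do.call(c, unname(sim$sim$orthologGenome))
    ort_aln <- if (length(g3ids))
      toySplicedAlign(flncSequences(flnc$flnc)[g3ids], ort_genome)
    else SplicedAlignments()
    bridges <- detectContigBridges(
      classify$groups, map$aln, ort_aln,
      setNames(Biostrings::nchar(sim$sim$draftContigs),
               names(sim$sim$draftContigs)))
    ## rescue of G4/G5 reads
    g45 <- classify$groups$read_id[classify$groups$group %in% c("G4", "G5")]
    rescue <- if (length(g45))
      rescueUnmapped(flncSequences(flnc$flnc)[g45],
                     sim$sim$orthologGeneSets)
    else list(matches = data.frame(), counts = c(Au = 0L, Dt = 0L))
    ## ORF completeness against the reference cDNA set
    cdna_aln <- if (length(sim$sim$cdnas))
      toySplicedAlign(sim$sim$cdnas, sim$sim$draftContigs)
    else SplicedAlignments()
    g1ids <- classify$groups$read_id[classify$groups$group == "G1"]
    best <- .best_per_read(map$aln)
    orf <- estimateOrfCompleteness(
      SplicedAlignments(best[best$read_id %in% g1ids, , drop = FALSE]),
      cdna_aln, sim$sim$cdnas)
    list(hq = hq, loci = loci, bridges = bridges, rescue = rescue,
         orf = orf)
  })
  isoforms <- .run_stage("isoforms", outdir, resume, function() {
    iso <- collapseIsoforms(annotate$hq, annotate$loci, map$aln,
                            sim$sim$draftModels)
    ## merge candidates: representative sequences vs ortholog genome
    reps <- flncSequences(flnc$flnc)[iso$representative_read]
    names(reps) <- iso$transcript_id
    ort_genome <- do.call(c, unname(sim$sim$orthologGenome))
    ort_models <- suppressWarnings(Reduce(function(a, b)
      GeneModelSet(c(modelExons(a), modelExons(b))),
      sim$sim$orthologModels))
    ort_aln <- toySplicedAlign(reps, ort_genome)
    merges <- detectSpanningTranscripts(iso, sim$sim$draftModels, ort_aln,
                                        ort_models, sequences = reps)
    list(isoforms = iso, merges = merges)
  })
  express <- .run_stage("express", outdir, resume, function() {
    iso <- isoforms$isoforms
    tx_table <- data.frame(transcript_id = iso$transcript_id,
                           gene_id = iso$locus_id, contig = iso$contig,
                           strand = iso$strand, stringsAsFactors = FALSE)
    tx_table$blocks <- iso$blocks
    ev <- shortReadEvidence(sim$short, tx_table, sim$sim$draftContigs)
    glen <- vapply(split(seq_len(nrow(iso)), iso$locus_id), function(ii) {
      b <- do.call(rbind, iso$blocks[ii])
      sum(IRanges::width(reduce(IRanges(b[, "tstart"], b[, "tend"]))))
    }, 0)
    expr <- callExpressedGenes(ev, glen)
    pres <- isoformPresence(iso, ev)
    diff <- differentialIsoformTable(pres, iso)
    list(evidence = ev, expression = expr, presence = pres,
         differential = diff)
  })
  report <- .build_report(flnc, classify, annotate, isoforms, express)
  out <- list(config = config, outdir = outdir, sim = sim, flnc = flnc,
              map = map, classify = classify, annotate = annotate,
              isoforms = isoforms, express = express, report = report)
  class(out) <- "IsoScanRun"
  out
}

# distinct junction-chain transcripts observed among G1 reads, plus the
# annotated models, as a tx_table for short-read matching
.candidate_tx_table <- function(groups, aln, models) {
  best <- .best_per_read(aln)
  g1 <- groups[groups$group == "G1", , drop = FALSE]
  best <- best[best$read_id %in% g1$read_id, , drop = FALSE]
  strand_of <- setNames(g1$strand, g1$read_id)
  key <- vapply(seq_len(nrow(best)), function(i)
    paste(best$contig[i],
          paste(sprintf("%d-%d", best$blocks[[i]][, "tstart"],
                        best$blocks[[i]][, "tend"]), collapse = ";")), "")
  keep <- !duplicated(key)
  cand <- data.frame(
    transcript_id = paste0("cand_", best$read_id[keep]),
    gene_id = paste0("cand_", best$read_id[keep]),
    contig = best$contig[keep],
    strand = unname(strand_of[best$read_id[keep]]),
    stringsAsFactors = FALSE)
  cand$blocks <- best$blocks[keep]
  mex <- modelExons(models)
  if (length(mex)) {
    sp <- split(seq_along(mex), mcols(mex)$transcript_id)
    mrow <- lapply(names(sp), function(tx) {
      ii <- sp[[tx]][order(start(mex)[sp[[tx]]])]
      r <- data.frame(transcript_id = tx,
                      gene_id = mcols(mex)$gene_id[ii[1]],
                      contig = as.character(seqnames(mex))[ii[1]],
                      strand = as.character(strand(mex))[ii[1]],
                      stringsAsFactors = FALSE)
      r$blocks <- list(cbind(qstart = 0L, qend = 0L,
                             tstart = start(mex)[ii], tend = end(mex)[ii]))
      r
    })
    cand <- rbind(do.call(rbind, mrow), cand)
  }
  ## locus-level grouping for the unique-mapper rule: overlapping spans on
  ## one contig are one locus (model and read-derived transcripts together)
  sp <- GRanges(cand$contig,
                IRanges(vapply(cand$blocks, function(b)
                  min(b[, "tstart"]), 0L),
                        vapply(cand$blocks, function(b)
                          max(b[, "tend"]), 0L)))
  cand$locus_group <- paste0("lg", GenomicRanges::findOverlaps(
    sp, reduce(sp), select = "first"))
  cand
}

# junction validation ignoring strand (short-read junction strand is not
# tracked by the transcript-matching evidence)
.validate_no_strand <- function(lj, sj) {
  key <- function(d) paste(d$contig, d$donor, d$acceptor)
  sup <- key(sj)[sj$support_count >= 1L]
  lj$supported <- key(lj) %in% sup
  uj <- lj[!duplicated(key(lj)), , drop = FALSE]
  mt <- table(.classify_motif(uj$motif))
  list(junctions = lj,
       supported_fraction = if (nrow(lj)) mean(lj$supported) else NA_real_,
       motif_table = round(100 * mt / sum(mt), 2))
}

.build_report <- function(flnc, classify, annotate, isoforms, express) {
  st <- flnc$stats
  grp <- table(factor(classify$groups$group,
                      levels = c("G1", "G2", "G3", "G4", "G5",
                                 "UNDETERMINED")))
  loci <- annotate$loci$loci
  iso <- isoforms$isoforms
  hq_n <- length(annotate$hq$kept)
  counts <- list(
    n_clr = st$n_clr, n_subreads = st$n_subreads, n_ccs = st$n_ccs,
    flnc_type_I = st$n_flnc_type_I, flnc_type_II = st$n_flnc_type_II,
    flnc_total = st$n_flnc,
    correction = flnc$correction,
    groups = grp,
    hq_total = hq_n,
    hq_excluded = sum(grp[["G1"]]) - hq_n,
    loci_extant = sum(loci$status == "EXTANT"),
    loci_novel = sum(loci$status == "NOVEL"),
    transcripts_known = sum(iso$status == "KNOWN"),
    transcripts_new_at_known = sum(iso$status == "NOVEL_AT_KNOWN_LOCUS"),
    transcripts_at_novel = sum(iso$status == "NOVEL_LOCUS"),
    transcripts_total = nrow(iso),
    expressed_per_stage = vapply(express$expression$expressed, length, 0L),
    differential_genes = sum(express$differential$differential),
    junction_supported_fraction =
      classify$junction_validation$supported_fraction,
    motif_table = classify$junction_validation$motif_table)
  ## additive identities (hard assertions)
  stopifnot(
    counts$flnc_total == counts$flnc_type_I + counts$flnc_type_II,
    sum(counts$groups) == counts$flnc_total,
    counts$hq_total == sum(counts$groups[["G1"]]) - counts$hq_excluded,
    counts$loci_extant + counts$loci_novel == nrow(loci),
    counts$transcripts_known + counts$transcripts_new_at_known +
      counts$transcripts_at_novel == counts$transcripts_total,
    sum(iso$n_supporting_reads) == counts$hq_total)
  counts
}

#' @export
print.IsoScanRun <- function(x, ...) {
  r <- x$report
  cat("IsoScan pipeline run\n")
  cat(sprintf("  CLRs %d -> subreads %d -> CCS %d -> FLNC %d (I %d / II %d)\n",
              r$n_clr, r$n_subreads, r$n_ccs, r$flnc_total, r$flnc_type_I,
              r$flnc_type_II))
  cat("  groups:", paste(names(r$groups), as.integer(r$groups),
                         sep = "=", collapse = " "), "\n")
  cat(sprintf("  high-quality %d; loci %d extant / %d novel; transcripts %d\n",
              r$hq_total, r$loci_extant, r$loci_novel, r$transcripts_total))
  cat("  expressed genes per stage:",
      paste(names(r$expressed_per_stage), r$expressed_per_stage, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}
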