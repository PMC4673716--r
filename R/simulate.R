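## Synthetic wheat-like dataset with planted ground truth.  The generator
## emulates a hexaploid draft genome: three subgenomes of homoeologous gene
## copies, draft contigs that split single genes, adjacent mis-split gene
## models, loci missing from the annotation or from the assembly, multi-pass
## long reads with primer/poly(A) structure and stage-specific short-read
## libraries.  Every simulated entity is recorded in a truth table so that
## each pipeline stage can be scored against what was planted.

#' Default cDNA synthesis primers and SMRTbell-style adapter
#'
#' The 5'/3' primers and the hairpin adapter used by the read generator and
#' expected by [classifyFlnc].  Configurable everywhere; these are the
#' package defaults.
#' @return named character vector with `p5`, `p3`, `adapter`
#' @export
isoPrimers <- function() {
  c(p5 = "AAGCAGTGGTATCAACGCAGAGTACATGGGG",
    p3 = "CGCAGGTTCAACTCTGCAACGGTCTAGTTCA",
    adapter = "ATCTCTCTCTTTTCCTCCTCCTCCGTTGTTGTTGTTGAGAGAGAT")
}

#' Simulation configuration
#'
#' Parameters of the synthetic dataset.  Fractions partition the gene
#' families into planted classes: `contig_split_fraction` genes are split
#' across two draft contigs (cross-contig reads), `model_missplit_fraction`
#' are annotated as two or three adjacent models (merge candidates),
#' `unannotated_fraction` are present in the contigs but absent from the
#' GFF3 (novel loci), `identical_homoeolog_fraction` have indistinguishable
#' copies (multi-mapping reads), `partial_gene_fraction` are only partially
#' and divergently covered by the draft (low-quality alignments) and
#' `absent_gene_fraction` are missing from the draft entirely (unmapped
#' reads).
#'
#' @param seed integer seed; all generator randomness derives from it
#' @param n_true_genes number of gene families
#' @param n_subgenomes homoeologous copies per family
#' @param homoeolog_divergence pairwise substitution divergence between
#'   homoeologous copies
#' @param contig_split_fraction fraction of families split across two contigs
#' @param model_missplit_fraction fraction annotated as 2-3 adjacent models
#' @param unannotated_fraction fraction absent from the draft GFF3
#' @param identical_homoeolog_fraction fraction with identical copies
#' @param partial_gene_fraction fraction with partial, diverged draft coverage
#' @param absent_gene_fraction fraction absent from the draft contigs
#' @param n_clr_reads number of continuous long reads
#' @param passes_distribution named numeric vector: probability per pass count
#' @param per_base_error raw per-base error rate of each pass
#' @param chimera_rate fraction of chimeric reads
#' @param truncation_rate fraction of 5'-truncated cDNA inserts
#' @param low_score_rate fraction of reads with sub-threshold read score
#' @param polya_length poly(A) tail length appended to each insert
#' @param n_stages number of developmental stages
#' @param short_read_length short-read length in bp
#' @param short_read_depth mean per-transcript short-read coverage per stage
#' @param cdna_fraction fraction of families with a reference full-length cDNA
#' @return a validated list of class `SimConfig`
#' @export
simConfig <- function(seed = 1L,
                      n_true_genes = 200L,
                      n_subgenomes = 3L,
                      homoeolog_divergence = 0.03,
                      contig_split_fraction = 0.05,
                      model_missplit_fraction = 0.05,
                      unannotated_fraction = 0.10,
                      identical_homoeolog_fraction = 0.06,
                      partial_gene_fraction = 0.04,
                      absent_gene_fraction = 0.03,
                      n_clr_reads = 5000L,
                      passes_distribution = c(`1` = 0.12, `2` = 0.10,
                                              `3` = 0.10, `4` = 0.10,
                                              `5` = 0.10, `6` = 0.12,
                                              `7` = 0.12, `8` = 0.10,
                                              `9` = 0.06, `10` = 0.04,
                                              `11` = 0.02, `12` = 0.02),
                      per_base_error = 0.12,
                      chimera_rate = 0.02,
                      truncation_rate = 0.08,
                      low_score_rate = 0.05,
                      polya_length = 30L,
                      n_stages = 4L,
                      short_read_length = 101L,
                      short_read_depth = 20,
                      cdna_fraction = 0.3) {
  cfg <- list(seed = as.integer(seed), n_true_genes = as.integer(n_true_genes),
              n_subgenomes = as.integer(n_subgenomes),
              homoeolog_divergence = homoeolog_divergence,
              contig_split_fraction = contig_split_fraction,
              model_missplit_fraction = model_missplit_fraction,
              unannotated_fraction = unannotated_fraction,
              identical_homoeolog_fraction = identical_homoeolog_fraction,
              partial_gene_fraction = partial_gene_fraction,
              absent_gene_fraction = absent_gene_fraction,
              n_clr_reads = as.integer(n_clr_reads),
              passes_distribution = passes_distribution,
              per_base_error = per_base_error,
              chimera_rate = chimera_rate,
              truncation_rate = truncation_rate,
              low_score_rate = low_score_rate,
              polya_length = as.integer(polya_length),
              n_stages = as.integer(n_stages),
              short_read_length = as.integer(short_read_length),
              short_read_depth = short_read_depth,
              cdna_fraction = cdna_fraction)
  fr <- c(cfg$contig_split_fraction, cfg$model_missplit_fraction,
          cfg$unannotated_fraction, cfg$identical_homoeolog_fraction,
          cfg$partial_gene_fraction, cfg$absent_gene_fraction,
          cfg$chimera_rate, cfg$truncation_rate, cfg$low_score_rate,
          cfg$cdna_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must be in [0, 1]")
  if (sum(fr[1:6]) > 1) stop("planted class fractions must sum to <= 1")
  if (cfg$n_subgenomes < 1L) stop("n_subgenomes must be >= 1")
  if (cfg$per_base_error < 0 || cfg$per_base_error >= 0.5)
    stop("per_base_error must be in [0, 0.5)")
  if (abs(sum(cfg$passes_distribution) - 1) > 1e-6)
    stop("passes_distribution must sum to 1")
  class(cfg) <- "SimConfig"
  cfg
}

.BASES <- c("A", "C", "G", "T")

.rand_seq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                               collapse = "")

# substitution-only mutation; keeps coordinates stable across copies
.mutate <- function(seq, rate, protect = integer(0)) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  hit <- which(runif(n) < rate)
  hit <- setdiff(hit, protect)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(.BASES, b), 1L), "")
  }
  paste(ch, collapse = "")
}

.revcomp_chr <- function(s)
  as.character(reverseComplement(DNAString(s)))

# sample an exon/intron structure whose transcript length falls in the
# realistic mRNA range
.sample_structure <- function(min_len = 575L, max_len = 4600L) {
  repeat {
    ne <- sample(c(1:12), 1L,
                 prob = c(0.10, 0.14, 0.14, 0.13, 0.12, 0.10, 0.08, 0.06,
                          0.05, 0.04, 0.02, 0.02))
    if (ne == 1L) {
      el <- sample(600:2400, 1L)    # single-exon genes (storage-protein-like)
    } else {
      el <- sample(80:600, ne, replace = TRUE)
    }
    if (sum(el) >= min_len && sum(el) <= max_len) {
      il <- if (ne > 1L) sample(60:2000, ne - 1L, replace = TRUE) else integer(0)
      return(list(n_exons = ne, exon_len = el, intron_len = il))
    }
  }
}

# give the transcript a clean ORF: 5' UTR, ATG, stop-free codons, terminal TAA
.plant_orf <- function(txseq) {
  ch <- strsplit(txseq, "")[[1]]
  L <- length(ch)
  utr5 <- min(120L, max(30L, round(L * 0.08)))
  utr3 <- min(150L, max(30L, round(L * 0.08)))
  orf_len <- ((L - utr5 - utr3) %/% 3L) * 3L
  orf_start <- utr5 + 1L
  orf_end <- orf_start + orf_len - 1L
  ch[orf_start:(orf_start + 2L)] <- c("A", "T", "G")
  ch[(orf_end - 2L):orf_end] <- c("T", "A", "A")
  # recode internal in-frame stops
  for (p in seq(orf_start + 3L, orf_end - 5L, by = 3L)) {
    cod <- paste(ch[p:(p + 2L)], collapse = "")
    if (cod %in% c("TAA", "TAG", "TGA")) ch[p] <- "C"
  }
  list(seq = paste(ch, collapse = ""), orf_start = orf_start,
       orf_end = orf_end)
}

.intron_motifs <- function(n) {
  m <- sample(c("GT-AG", "GC-AG", "AT-AC"), n, replace = TRUE,
              prob = c(0.975, 0.02, 0.005))
  m
}

#' Simulate the draft genome, annotation, ortholog references and truth
#'
#' Builds the complete genomic side of the synthetic dataset: draft contigs
#' (with planted split, partial and absent genes), a draft GFF3 with planted
#' mis-split and missing models, two contiguous ortholog reference genomes
#' with correct single-gene annotations, ortholog transcript sets for rescue
#' and a reference full-length cDNA set, plus the ground-truth tables tying
#' everything together.
#'
#' @param config a [simConfig] object
#' @return a list of class `IsoSim` with elements `draftContigs`,
#'   `draftModels`, `orthologGenome`, `orthologModels`, `orthologGeneSets`,
#'   `cdnas`, `contigSubgenome` and `truth` (gene/transcript/exon/ORF tables,
#'   stage presence and abundance)
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  nf <- config$n_true_genes
  subs <- c("A", "B", "D")[seq_len(config$n_subgenomes)]

  ## ---- role assignment -----------------------------------------------
  n_split <- round(config$contig_split_fraction * nf)
  n_missplit <- round(config$model_missplit_fraction * nf)
  n_novel <- round(config$unannotated_fraction * nf)
  n_g2 <- round(config$identical_homoeolog_fraction * nf)
  n_g4 <- round(config$partial_gene_fraction * nf)
  n_g5 <- round(config$absent_gene_fraction * nf)

  structures <- lapply(seq_len(nf), function(i) .sample_structure())
  roles <- rep("normal", nf)
  multi4 <- which(vapply(structures, `[[`, 0L, "n_exons") >= 4L)
  need_multi <- n_split + n_missplit
  if (length(multi4) < need_multi)
    stop("infeasible config: too few multi-exon genes for split/missplit roles")
  pick <- sample(multi4, need_multi)
  roles[pick[seq_len(n_split)]] <- "split"
  if (n_missplit) roles[pick[n_split + seq_len(n_missplit)]] <- "missplit"
  # the partial-coverage class needs genes whose exon chain has a prefix
  # holding 34-46 % of the transcript, so the draft fragment lands cleanly
  # inside the 30-50 % coverage band
  g4_ok <- vapply(structures, function(st) {
    if (st$n_exons < 2L) return(FALSE)
    cf <- cumsum(st$exon_len) / sum(st$exon_len)
    any(cf[-st$n_exons] >= 0.34 & cf[-st$n_exons] <= 0.46)
  }, TRUE)
  rest_multi <- setdiff(which(roles == "normal" & g4_ok), pick)
  if (length(rest_multi) < n_g4)
    stop("infeasible config: too few multi-exon genes for the partial class")
  g4_pick <- sample(rest_multi, n_g4)
  roles[g4_pick] <- "g4"
  rest <- which(roles == "normal")
  pick2 <- sample(rest, n_novel + n_g2 + n_g5)
  i0 <- 0L
  for (rr in list(c("novel", n_novel), c("g2", n_g2), c("g5", n_g5))) {
    k <- as.integer(rr[2])
    if (k) roles[pick2[i0 + seq_len(k)]] <- rr[1]
    i0 <- i0 + k
  }

  genes <- list(); txs <- list(); exon_rows <- list()
  contigs <- list(); model_rows <- list()
  ort_regions <- list(Au = list(), Dt = list())
  ort_tx <- list(Au = list(), Dt = list())
  cdna_list <- list()
  g2_subtype <- c("a", "b", "c")
  g2_i <- 0L
  novel_share <- logical(nf)   # novel loci sharing a contig with a model
  normal_fams <- which(roles == "normal")

  contig_serial <- 0L
  new_ctg_name <- function(sub) {
    contig_serial <<- contig_serial + 1L
    chrom <- sample(1:7, 1L); arm <- sample(c("S", "L"), 1L)
    sprintf("%d%s%s_%05d", chrom, sub, arm, contig_serial)
  }

  for (f in seq_len(nf)) {
    st <- structures[[f]]
    fam <- sprintf("F%03d", f)
    role <- roles[f]
    ne <- st$n_exons
    ## ancestral gene
    tx0 <- .rand_seq(sum(st$exon_len))
    orf <- .plant_orf(tx0)
    tx0 <- orf$seq
    cuts <- cumsum(st$exon_len)
    exon_seq <- substring(tx0, c(1L, head(cuts, -1) + 1L), cuts)
    motifs <- .intron_motifs(max(ne - 1L, 0L))
    intron_seq <- character(0)
    if (ne > 1L) {
      intron_seq <- vapply(seq_len(ne - 1L), function(i) {
        s <- .rand_seq(st$intron_len[i])
        mo <- strsplit(motifs[i], "-")[[1]]
        paste0(mo[1], substr(s, 3L, nchar(s) - 2L), mo[2])
      }, "")
    }
    ## isoforms: 1 = all exons; extras skip one internal exon.  Split and
    ## partial-coverage families stay single-isoform so their planted
    ## per-contig coverage bands are not shifted by exon skipping.
    n_iso <- if (ne >= 3L && !role %in% c("split", "g4"))
      sample(1:3, 1L, prob = c(0.5, 0.35, 0.15)) else 1L
    skippable <- if (ne >= 3L) seq.int(2L, ne - 1L) else integer(0)
    n_iso <- min(n_iso, 1L + length(skippable))
    skip <- if (n_iso > 1L)
      skippable[sample.int(length(skippable), n_iso - 1L)]
    else integer(0)
    iso_exons <- c(list(seq_len(ne)),
                   lapply(skip, function(s) setdiff(seq_len(ne), s)))

    ## protected positions (region coords of ancestral gene, flanks excluded)
    flank5 <- .rand_seq(400L); flank3 <- .rand_seq(400L)
    # region layout: exon/intron starts within the gene body (no flanks yet)
    body_parts <- character(0)
    exon_body_start <- integer(ne)
    pos <- 0L
    for (i in seq_len(ne)) {
      exon_body_start[i] <- pos + 1L
      body_parts <- c(body_parts, exon_seq[i])
      pos <- pos + nchar(exon_seq[i])
      if (i < ne) {
        body_parts <- c(body_parts, intron_seq[i])
        pos <- pos + nchar(intron_seq[i])
      }
    }
    body <- paste(body_parts, collapse = "")
    tx2body <- function(p) {     # transcript coord -> body coord
      i <- findInterval(p, c(1L, head(cuts, -1) + 1L))
      exon_body_start[i] + (p - c(0L, head(cuts, -1))[i]) - 1L
    }
    protect <- c(vapply(orf$orf_start:(orf$orf_start + 2L), tx2body, 0L),
                 vapply((orf$orf_end - 2L):orf$orf_end, tx2body, 0L))
    if (ne > 1L) {
      istart <- exon_body_start[-1] - st$intron_len
      iend <- exon_body_start[-1] - 1L
      protect <- c(protect, istart, istart + 1L, iend - 1L, iend)
    }

    ## per-copy divergence
    rate <- if (role == "g2") 0 else config$homoeolog_divergence / 2
    sub_copies <- subs
    if (role == "g2") {
      g2_i <- g2_i + 1L
      sub_copies <- switch(g2_subtype[(g2_i - 1L) %% 3L + 1L],
                           a = subs,
                           b = c(subs[1], subs[1]),
                           c = if (length(subs) >= 2L)
                                 c(subs[1], subs[1], subs[length(subs)])
                               else c(subs[1], subs[1]))
    }

    for (ci in seq_along(sub_copies)) {
      s <- sub_copies[ci]
      gid <- sprintf("G%03d%s%s", f, s, if (role == "g2") ci else "")
      gbody <- .mutate(body, rate, protect)
      gstrand <- sample(c("+", "-"), 1L)
      region <- paste0(flank5, gbody, flank3)
      exon_region_start <- exon_body_start + 400L
      exon_region_end <- exon_region_start + st$exon_len - 1L
      Lr <- nchar(region)

      ctg_info <- NULL
      if (role == "split") {
        ## break inside the intron whose upstream exons hold 36-64 % of
        ## the transcript
        cumfrac <- cumsum(st$exon_len) / sum(st$exon_len)
        cand <- which(cumfrac >= 0.36 & cumfrac <= 0.64 &
                        seq_len(ne) < ne)
        if (!length(cand)) cand <- which.min(abs(cumfrac - 0.5))
        b <- cand[1]
        ## each contig keeps <= 100 bp of the breakpoint intron; the intron
        ## middle is simply absent from the draft (what fragmentation loses),
        ## so both gene halves end close to their contig ends
        keepi <- min(100L, st$intron_len[b] %/% 3L)
        cut_at <- exon_region_end[b] + keepi
        cut_b <- exon_region_start[b + 1L] - keepi
        partA <- substr(region, 1L, cut_at)
        partB <- substr(region, cut_b, Lr)
        ctgA <- new_ctg_name(s); ctgB <- new_ctg_name(s)
        if (gstrand == "+") {
          contigs[[ctgA]] <- partA; contigs[[ctgB]] <- partB
          exA <- seq_len(b); exB <- (b + 1L):ne
          exon_ctg <- c(rep(ctgA, b), rep(ctgB, ne - b))
          exon_s <- c(exon_region_start[exA],
                      exon_region_start[exB] - (cut_b - 1L))
          exon_e <- c(exon_region_end[exA],
                      exon_region_end[exB] - (cut_b - 1L))
          exon_str <- rep("+", ne)
        } else {
          contigs[[ctgA]] <- .revcomp_chr(partA)
          contigs[[ctgB]] <- .revcomp_chr(partB)
          LA <- nchar(partA); LB <- nchar(partB)
          exon_ctg <- c(rep(ctgA, b), rep(ctgB, ne - b))
          exon_s <- c(LA - exon_region_end[seq_len(b)] + 1L,
                      LB - (exon_region_end[(b + 1L):ne] - (cut_b - 1L)) + 1L)
          exon_e <- c(LA - exon_region_start[seq_len(b)] + 1L,
                      LB - (exon_region_start[(b + 1L):ne] - (cut_b - 1L)) + 1L)
          exon_str <- rep("-", ne)
        }
        ctg_info <- list(contig = ctgA, contig2 = ctgB)
      } else if (role == "g5") {
        exon_ctg <- rep(NA_character_, ne)
        exon_s <- exon_region_start; exon_e <- exon_region_end
        exon_str <- rep(gstrand, ne)
        ctg_info <- list(contig = NA_character_, contig2 = NA_character_)
      } else if (role == "g4") {
        ## draft holds a further-diverged prefix of the gene (34-46 % of
        ## exonic content), the rest is missing
        cumfrac <- cumsum(st$exon_len) / sum(st$exon_len)
        band <- which(cumfrac >= 0.34 & cumfrac <= 0.46 & seq_len(ne) < ne)
        k <- if (length(band)) band[which.min(abs(cumfrac[band] - 0.40))]
             else max(1L, which.min(abs(cumfrac[-ne] - 0.40)))
        keep_end <- exon_region_end[k] + 50L
        part <- substr(region, 1L, min(keep_end, Lr))
        part <- .mutate(part, 0.14)
        ctg <- new_ctg_name(s)
        contigs[[ctg]] <- if (gstrand == "+") part else .revcomp_chr(part)
        ## truth exons refer to the (unmapped) true gene; the draft copy is
        ## deliberately partial and diverged
        exon_ctg <- rep(NA_character_, ne)
        exon_s <- exon_region_start; exon_e <- exon_region_end
        exon_str <- rep(gstrand, ne)
        ctg_info <- list(contig = ctg, contig2 = NA_character_)
      } else {
        ctg <- new_ctg_name(s)
        share <- FALSE
        offset <- 0L
        if (role == "novel" && ci == 1L && (f %% 2L == 0L) &&
            length(normal_fams)) {
          share <- TRUE    # half the novel loci share a contig with a model
        }
        if (gstrand == "+") {
          contigs[[ctg]] <- region
          exon_s <- exon_region_start; exon_e <- exon_region_end
        } else {
          contigs[[ctg]] <- .revcomp_chr(region)
          exon_s <- Lr - exon_region_end + 1L
          exon_e <- Lr - exon_region_start + 1L
        }
        exon_ctg <- rep(ctg, ne)
        exon_str <- rep(gstrand, ne)
        ctg_info <- list(contig = ctg, contig2 = NA_character_,
                         share = share)
      }

      ## truth exon rows (ascending genomic order per contig)
      ord <- order(exon_ctg, exon_s)
      for (iso in seq_along(iso_exons)) {
        tid <- sprintf("%s.%d", gid, iso)
        ii <- iso_exons[[iso]]
        txseq <- paste(vapply(ii, function(e) {
          # copy exon sequence = region substring (strand-aware later)
          substr(gbody, exon_body_start[e],
                 exon_body_start[e] + st$exon_len[e] - 1L)
        }, ""), collapse = "")
        txs[[length(txs) + 1L]] <- data.frame(
          tx_id = tid, gene_id = gid, family = fam, subgenome = s,
          isoform = iso, length = nchar(txseq), sequence = txseq,
          strand = gstrand, stringsAsFactors = FALSE)
        keep <- which(seq_len(ne) %in% ii)
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          tx_id = tid, gene_id = gid, exon = keep,
          contig = exon_ctg[keep], start = exon_s[keep], end = exon_e[keep],
          strand = exon_str[keep], stringsAsFactors = FALSE)
      }

      ## draft gene models
      annotate <- !role %in% c("novel", "g5", "g4")
      if (annotate) {
        mk_model <- function(model_id, exon_idx, part = 1L) {
          data.frame(gene_id = model_id,
                     transcript_id = paste0(model_id, ".m1"),
                     contig = exon_ctg[exon_idx], start = exon_s[exon_idx],
                     end = exon_e[exon_idx], strand = exon_str[exon_idx],
                     stringsAsFactors = FALSE)
        }
        if (role == "missplit") {
          k <- max(2L, ne %/% 2L)
          nparts <- if (ne >= 6L) 3L else 2L
          bounds <- round(seq(0, ne, length.out = nparts + 1L))
          for (p in seq_len(nparts)) {
            idx <- (bounds[p] + 1L):bounds[p + 1L]
            model_rows[[length(model_rows) + 1L]] <-
              mk_model(sprintf("%s.p%d", gid, p), idx)
          }
        } else if (role == "split") {
          onA <- which(exon_ctg == ctg_info$contig)
          onB <- which(exon_ctg == ctg_info$contig2)
          model_rows[[length(model_rows) + 1L]] <-
            mk_model(paste0(gid, ".p1"), onA)
          model_rows[[length(model_rows) + 1L]] <-
            mk_model(paste0(gid, ".p2"), onB)
        } else {
          model_rows[[length(model_rows) + 1L]] <-
            mk_model(gid, seq_len(ne))
        }
      }

      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, family = fam, subgenome = s, role = role,
        status = switch(role, novel = "novel", missplit = "missplit",
                        split = "split_across_contigs", g4 = "partial",
                        g5 = "absent", "extant"),
        contig = ctg_info$contig, contig2 = ctg_info$contig2,
        strand = gstrand, n_exons = ne,
        share_contig = isTRUE(ctg_info$share), stringsAsFactors = FALSE)
    }

    ## ortholog references: contiguous, correctly annotated single gene
    for (sp in c("Au", "Dt")) {
      oseq <- .mutate(body, 0.02, protect)
      ort_regions[[sp]][[fam]] <- list(
        seq = oseq, exon_start = exon_body_start,
        exon_end = exon_body_start + st$exon_len - 1L, family = fam)
      ospl <- paste(substring(oseq, exon_body_start,
                              exon_body_start + st$exon_len - 1L),
                    collapse = "")
      ort_tx[[sp]][[fam]] <- ospl
    }

    ## reference full-length cDNA for a subset of ordinary families
    if (role == "normal" && runif(1) < config$cdna_fraction) {
      cdna_list[[paste0("cdna_", fam)]] <-
        txs[[length(txs) - length(iso_exons) * (length(sub_copies) - 1L) -
               length(iso_exons) + 1L]]$sequence[1]
    }
  }

  gene_tab <- do.call(rbind, genes)
  tx_tab <- do.call(rbind, txs)
  exon_tab <- do.call(rbind, exon_rows)

  ## merge shared-contig novel loci onto a partner contig with a model
  novel_genes <- which(gene_tab$role == "novel" & gene_tab$share_contig)
  partner_pool <- gene_tab$gene_id[gene_tab$role == "normal"]
  for (gi in novel_genes) {
    if (!length(partner_pool)) break
    pg <- partner_pool[1]; partner_pool <- partner_pool[-1]
    pctg <- gene_tab$contig[gene_tab$gene_id == pg]
    nctg <- gene_tab$contig[gi]
    off <- nchar(contigs[[pctg]]) + 500L
    contigs[[pctg]] <- paste0(contigs[[pctg]], .rand_seq(500L),
                              contigs[[nctg]])
    contigs[[nctg]] <- NULL
    sel <- !is.na(exon_tab$contig) & exon_tab$contig == nctg
    exon_tab$start[sel] <- exon_tab$start[sel] + off
    exon_tab$end[sel] <- exon_tab$end[sel] + off
    exon_tab$contig[sel] <- pctg
    gene_tab$contig[gi] <- pctg
  }

  ## ortholog genomes: concatenate family regions, 5 per contig
  ort_genome <- list(); ort_models <- list()
  for (sp in c("Au", "Dt")) {
    regs <- ort_regions[[sp]]
    fams <- names(regs)
    grpix <- split(seq_along(fams), ceiling(seq_along(fams) / 5))
    seqs <- c(character(0)); mrows <- list()
    for (g in seq_along(grpix)) {
      cname <- sprintf("%s_ctg%03d", sp, g)
      parts <- character(0); pos <- 0L
      for (i in grpix[[g]]) {
        spacer <- 400L
        parts <- c(parts, paste(rep("N", 0L), collapse = ""),
                   .rand_seq(spacer), regs[[i]]$seq)
        gstart <- pos + spacer
        mrows[[length(mrows) + 1L]] <- data.frame(
          gene_id = paste0(sp, "_", fams[i]),
          transcript_id = paste0(sp, "_", fams[i], ".m1"),
          contig = cname, start = gstart + regs[[i]]$exon_start,
          end = gstart + regs[[i]]$exon_end, strand = "+",
          family = fams[i], stringsAsFactors = FALSE)
        pos <- pos + spacer + nchar(regs[[i]]$seq)
      }
      seqs[cname] <- paste(parts, collapse = "")
    }
    ort_genome[[sp]] <- DNAStringSet(seqs)
    ort_models[[sp]] <- .models_from_table(do.call(rbind, mrows))
  }

  draft_models <- .models_from_table(do.call(rbind, model_rows))

  ## stage presence and abundance
  n_tx <- nrow(tx_tab)
  stages <- paste0("S", seq_len(config$n_stages))
  pres <- matrix(FALSE, n_tx, config$n_stages,
                 dimnames = list(tx_tab$tx_id, stages))
  gene_ids <- unique(tx_tab$gene_id)
  gene_on <- matrix(FALSE, length(gene_ids), config$n_stages,
                    dimnames = list(gene_ids, stages))
  fam_of_gene <- setNames(gene_tab$family, gene_tab$gene_id)
  role_of_gene <- setNames(gene_tab$role, gene_tab$gene_id)
  g2_pattern <- list()
  for (g in seq_along(gene_ids)) {
    gid <- gene_ids[g]
    ## identical-copy families share one pattern: their copies cannot be
    ## told apart by uniquely mapping reads, so per-copy expression would
    ## be unrecoverable by construction
    if (role_of_gene[gid] == "g2" &&
        !is.null(g2_pattern[[fam_of_gene[gid]]])) {
      gene_on[g, ] <- g2_pattern[[fam_of_gene[gid]]]
      next
    }
    if (runif(1) < 0.6) gene_on[g, ] <- TRUE
    else {
      k <- sample(config$n_stages, 1L)
      gene_on[g, sample(config$n_stages, k)] <- TRUE
    }
    if (role_of_gene[gid] == "g2")
      g2_pattern[[fam_of_gene[gid]]] <- gene_on[g, ]
  }
  g2_iso_pattern <- list()
  for (i in seq_len(n_tx)) {
    gid <- tx_tab$gene_id[i]
    on <- gene_on[gid, ]
    if (tx_tab$isoform[i] == 1L) { pres[i, ] <- on; next }
    memo_key <- paste(fam_of_gene[gid], tx_tab$isoform[i])
    if (role_of_gene[gid] == "g2" && !is.null(g2_iso_pattern[[memo_key]])) {
      pres[i, ] <- g2_iso_pattern[[memo_key]]
      next
    }
    ons <- which(on)
    keepn <- sample(length(ons), 1L)
    pres[i, sample(ons, keepn)] <- TRUE
    if (role_of_gene[gid] == "g2") g2_iso_pattern[[memo_key]] <- pres[i, ]
  }
  abundance <- stats::rlnorm(n_tx, meanlog = 0, sdlog = 0.8)
  names(abundance) <- tx_tab$tx_id

  csub <- data.frame(contig = names(contigs),
                     subgenome = substr(names(contigs), 2L, 2L),
                     stringsAsFactors = FALSE)

  out <- list(
    draftContigs = DNAStringSet(unlist(contigs)),
    draftModels = draft_models,
    orthologGenome = ort_genome,
    orthologModels = ort_models,
    orthologGeneSets = lapply(ort_tx, function(x)
      DNAStringSet(setNames(unlist(x), paste0(names(x), "_tx")))),
    cdnas = DNAStringSet(unlist(cdna_list)),
    contigSubgenome = csub,
    truth = list(genes = gene_tab, transcripts = tx_tab, exons = exon_tab,
                 stage_presence = pres, abundance = abundance,
                 config = config))
  class(out) <- "IsoSim"
  out
}

# build a GeneModelSet from a flat exon table
.models_from_table <- function(tab) {
  if (is.null(tab) || !nrow(tab)) return(GeneModelSet())
  ord <- order(tab$gene_id, tab$transcript_id, tab$start)
  tab <- tab[ord, ]
  gr <- GRanges(tab$contig, IRanges(tab$start, tab$end), strand = tab$strand,
                gene_id = tab$gene_id, transcript_id = tab$transcript_id,
                exon_rank = unlist(lapply(
                  split(seq_len(nrow(tab)), tab$transcript_id)[
                    unique(tab$transcript_id)], seq_along),
                  use.names = FALSE))
  GeneModelSet(gr)
}

#' @export
print.IsoSim <- function(x, ...) {
  cat(sprintf("IsoSim: %d draft contigs (%.2f Mb), %d genes, %d transcripts\n",
              length(x$draftContigs),
              sum(Biostrings::nchar(x$draftContigs)) / 1e6,
              nrow(x$truth$genes), nrow(x$truth$transcripts)))
  print(table(x$truth$genes$role))
  invisible(x)
}

## ---------------------------------------------------------------------------
## long reads
## ---------------------------------------------------------------------------

# inject substitution/insertion/deletion errors (40:30:30) at `rate`
.inject_errors <- function(seq, rate) inject_errors_cpp(seq, rate)

#' Simulate continuous long reads (CLRs)
#'
#' Each CLR is a multi-pass read of one SMRTbell insert: alternating
#' sense/antisense copies of `5' primer + transcript + poly(A) + rc(3'
#' primer)`, separated by the hairpin adapter.  Per-base errors are injected
#' independently per pass.  Chimeric inserts concatenate two transcripts
#' with internal primers; truncated inserts lack one or more 5' exons.
#'
#' @param config a [simConfig]
#' @param sim result of [simulateGenome]
#' @return list with `reads` (`DNAStringSet`), `scores` (per-CLR read-score
#'   proxy) and `read_table` (truth: source transcript, chimera/truncation
#'   flags, planted mapping group, pass count, eligibility)
#' @export
simulateClrReads <- function(config, sim) {
  set.seed(config$seed + 1L)
  pr <- isoPrimers()
  tr <- sim$truth
  tx_tab <- tr$transcripts
  w <- tr$abundance * pmax(rowSums(tr$stage_presence), 0)
  w <- w[tx_tab$tx_id]
  role_of_gene <- setNames(tr$genes$role, tr$genes$gene_id)
  group_map <- c(normal = "G1", novel = "G1", missplit = "G1", split = "G3",
                 g2 = "G2", g4 = "G4", g5 = "G5")
  n <- config$n_clr_reads
  pick <- sample(seq_len(nrow(tx_tab)), n, replace = TRUE,
                 prob = if (sum(w) > 0) w else NULL)
  passes <- sample(as.integer(names(config$passes_distribution)), n,
                   replace = TRUE, prob = config$passes_distribution)
  chim <- runif(n) < config$chimera_rate
  trunc <- !chim & runif(n) < config$truncation_rate
  lowsc <- runif(n) < config$low_score_rate
  scores <- ifelse(lowsc, runif(n, 0.30, 0.74), runif(n, 0.76, 0.99))
  exon_dt <- as.data.table(tr$exons)
  reads <- character(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ti <- pick[i]
    txseq <- tx_tab$sequence[ti]
    trunc_exons <- 0L
    if (trunc[i]) {
      ex <- exon_dt[tx_id == tx_tab$tx_id[ti]]
      ne <- nrow(ex)
      if (ne >= 2L) {
        drop <- sample(seq_len(ne - 1L), 1L)
        # exon table rows are in transcription order (exon index)
        lens <- ex$end - ex$start + 1L
        txseq <- substr(txseq, sum(lens[seq_len(drop)]) + 1L, nchar(txseq))
        trunc_exons <- drop
      } else trunc[i] <- FALSE
    }
    mk_insert <- function(s)
      paste0(pr["p5"], s, strrep("A", config$polya_length),
             .revcomp_chr(pr["p3"]))
    insert <- mk_insert(txseq)
    if (chim[i]) {
      t2 <- sample(seq_len(nrow(tx_tab)), 1L)
      insert <- paste0(insert, mk_insert(tx_tab$sequence[t2]))
    }
    pieces <- character(passes[i])
    for (p in seq_len(passes[i])) {
      tmpl <- if (p %% 2L == 1L) insert else .revcomp_chr(insert)
      pieces[p] <- .inject_errors(tmpl, config$per_base_error)
    }
    adap <- vapply(seq_len(max(passes[i] - 1L, 0L)), function(j)
      .inject_errors(pr["adapter"], config$per_base_error), "")
    v <- character(2L * passes[i] - 1L)
    v[seq(1L, length(v), 2L)] <- pieces
    if (passes[i] > 1L) v[seq(2L, length(v), 2L)] <- adap
    reads[i] <- paste(v, collapse = "")
    rows[[i]] <- data.frame(
      read_id = sprintf("clr%05d", i), tx_id = tx_tab$tx_id[ti],
      gene_id = tx_tab$gene_id[ti], family = tx_tab$family[ti],
      n_passes = passes[i], is_chimera = chim[i],
      is_5prime_truncated = trunc[i], truncated_exons = trunc_exons,
      read_score = scores[i],
      ## 5'-truncation changes the mapping class of split/partial genes
      ## unpredictably (e.g. only one contig half left): no planted group
      group = if (chim[i] ||
                  (trunc[i] && role_of_gene[tx_tab$gene_id[ti]] %in%
                     c("split", "g4"))) NA_character_
              else unname(group_map[role_of_gene[tx_tab$gene_id[ti]]]),
      flnc_eligible = !chim[i] & scores[i] >= 0.75,
      stringsAsFactors = FALSE)
  }
  read_table <- do.call(rbind, rows)
  out <- DNAStringSet(reads)
  names(out) <- read_table$read_id
  list(reads = out, scores = setNames(scores, read_table$read_id),
       read_table = read_table)
}

## ---------------------------------------------------------------------------
## short reads
## ---------------------------------------------------------------------------

#' Simulate stage-specific short-read libraries
#'
#' Error-free reads of `short_read_length` bp sampled only from the
#' transcripts marked present at each stage.  With `tiling_step` set, reads
#' are generated deterministically at every `tiling_step` positions (so every
#' junction is guaranteed spanning coverage); otherwise read counts follow
#' the configured mean depth and abundance weights.
#'
#' @param config a [simConfig]
#' @param sim result of [simulateGenome]
#' @param tiling_step optional integer; deterministic tiling instead of
#'   random sampling
#' @return named list (one per stage) of `DNAStringSet`
#' @export
simulateShortReads <- function(config, sim, tiling_step = NULL) {
  set.seed(config$seed + 2L)
  tr <- sim$truth
  tx_tab <- tr$transcripts
  L <- config$short_read_length
  out <- list()
  for (s in seq_len(config$n_stages)) {
    stage <- paste0("S", s)
    pres <- tr$stage_presence[, s]
    seqs <- character(0); ids <- character(0)
    for (i in which(pres[tx_tab$tx_id])) {
      txseq <- tx_tab$sequence[i]
      n <- nchar(txseq)
      if (n < L) next
      if (!is.null(tiling_step)) {
        starts <- seq(1L, n - L + 1L, by = as.integer(tiling_step))
        if (tail(starts, 1L) != n - L + 1L) starts <- c(starts, n - L + 1L)
      } else {
        cnt <- rpois(1L, max(0, n * config$short_read_depth / L *
                                  tr$abundance[tx_tab$tx_id[i]] /
                                  mean(tr$abundance)))
        if (cnt == 0L) next
        starts <- sample(n - L + 1L, cnt, replace = TRUE)
      }
      seqs <- c(seqs, substring(txseq, starts, starts + L - 1L))
      ids <- c(ids, sprintf("%s_%s_%06d", stage, tx_tab$tx_id[i],
                            seq_along(starts)))
    }
    x <- DNAStringSet(seqs)
    names(x) <- ids
    out[[stage]] <- x
  }
  out
}

## ---------------------------------------------------------------------------
## gene-family (gluten-like) reads
## ---------------------------------------------------------------------------

#' Simulate a storage-protein-like gene family with full-length reads
#'
#' Generates `n_alleles` single-exon alleles of one family diverged pairwise
#' by at least `divergence`, each with a clean ORF.  One allele (the
#' pseudogene analogue) carries a premature stop codon at a planted codon
#' index.  Reads are full-length copies of the alleles with a small residual
#' error rate, emulating corrected FLNC reads.
#'
#' @param seed integer seed
#' @param n_alleles number of alleles
#' @param divergence minimum pairwise divergence between alleles
#' @param reads_per_allele reads generated per allele
#' @param error_rate residual per-base error on reads
#' @param orf_codons ORF length in codons
#' @param stop_codon_index planted premature stop (codon index within the
#'   ORF) in allele 1; `NA` for none
#' @return list with `alleles`, `reads` (`DNAStringSet`), `query`
#'   (ancestral family sequence), `read_table` and `stop_codon_index`
#' @export
simulateFamilyReads <- function(seed = 1L, n_alleles = 6L, divergence = 0.03,
                                reads_per_allele = 100L, error_rate = 0.01,
                                orf_codons = 280L, stop_codon_index = 120L) {
  set.seed(seed + 3L)
  utr5 <- 60L; utr3 <- 80L
  L <- utr5 + 3L * orf_codons + utr3
  anc <- .plant_orf(.rand_seq(L))
  # .plant_orf picks its own UTRs from length; recompute from its output
  orf_start <- anc$orf_start; orf_end <- anc$orf_end
  fix_orf <- function(seq) {
    ch <- strsplit(seq, "")[[1]]
    ch[orf_start:(orf_start + 2L)] <- c("A", "T", "G")
    ch[(orf_end - 2L):orf_end] <- c("T", "A", "A")
    for (p in seq(orf_start + 3L, orf_end - 5L, by = 3L)) {
      cod <- paste(ch[p:(p + 2L)], collapse = "")
      if (cod %in% c("TAA", "TAG", "TGA")) ch[p] <- "C"
    }
    ## scrub upstream ATGs so the planted start codon is unambiguous (an
    ## in-frame upstream ATG would shift every reported codon index)
    if (orf_start > 3L) {
      for (p in seq_len(orf_start - 3L)) {
        if (ch[p] == "A" && ch[p + 1L] == "T" && ch[p + 2L] == "G")
          ch[p + 2L] <- "C"
      }
    }
    paste(ch, collapse = "")
  }
  alleles <- character(n_alleles)
  for (a in seq_len(n_alleles)) {
    repeat {
      cand <- fix_orf(.mutate(anc$seq, divergence * 0.75))
      divs <- vapply(alleles[seq_len(a - 1L)], function(x) {
        mean(strsplit(cand, "")[[1]] != strsplit(x, "")[[1]])
      }, 0)
      if (a == 1L || all(divs >= divergence)) { alleles[a] <- cand; break }
    }
  }
  if (!is.na(stop_codon_index)) {
    ch <- strsplit(alleles[1], "")[[1]]
    p <- orf_start + 3L * (stop_codon_index - 1L)
    ch[p:(p + 2L)] <- c("T", "A", "G")
    alleles[1] <- paste(ch, collapse = "")
  }
  names(alleles) <- sprintf("allele%02d", seq_len(n_alleles))
  rows <- list(); seqs <- character(0)
  for (a in seq_len(n_alleles)) {
    for (r in seq_len(reads_per_allele)) {
      seqs <- c(seqs, .inject_errors(alleles[a], error_rate))
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("fam_a%02d_r%03d", a, r),
        allele = names(alleles)[a], stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  reads <- DNAStringSet(seqs); names(reads) <- tab$read_id
  list(alleles = DNAStringSet(alleles), reads = reads,
       query = DNAStringSet(c(HMWfam = fix_orf(anc$seq))),
       read_table = tab, stop_codon_index = stop_codon_index,
       orf_start = orf_start, orf_end = orf_end)
}
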