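test_that("config validation rejects out-of-range parameters", {
  expect_error(simConfig(per_base_error = 0.6), "per_base_error")
  expect_error(simConfig(contig_split_fraction = 1.2), "fractions")
  expect_error(simConfig(n_subgenomes = 0), "n_subgenomes")
  expect_error(simConfig(passes_distribution = c(`1` = 0.5, `2` = 0.4)),
               "sum to 1")
})

test_that("generator output is deterministic under a fixed seed", {
  cfg <- simConfig(seed = 11, n_true_genes = 8, n_clr_reads = 20)
  a <- simulateGenome(cfg); b <- simulateGenome(cfg)
  expect_identical(as.character(a$draftContigs), as.character(b$draftContigs))
  expect_identical(a$truth$genes, b$truth$genes)
  ra <- simulateClrReads(cfg, a); rb <- simulateClrReads(cfg, b)
  expect_identical(as.character(ra$reads), as.character(rb$reads))
  sa <- simulateShortReads(cfg, a); sb <- simulateShortReads(cfg, b)
  expect_identical(lapply(sa, as.character), lapply(sb, as.character))
})

test_that("planted gene classes are constructed as configured", {
  tf <- tiny_sim()
  genes <- tf$sim$truth$genes
  cfg <- tf$cfg
  n_split_fams <- length(unique(genes$family[genes$role == "split"]))
  expect_equal(n_split_fams, round(cfg$contig_split_fraction *
                                     cfg$n_true_genes))
  # each split copy sits on two contigs
  sp <- genes[genes$role == "split", ]
  expect_true(all(!is.na(sp$contig2)))
  ex <- tf$sim$truth$exons
  for (g in sp$gene_id)
    expect_equal(length(unique(ex$contig[ex$gene_id == g])), 2L)
  # unannotated genes absent from the GFF3 but present in the contigs
  nov <- genes[genes$role == "novel", ]
  ann_ids <- geneIds(tf$sim$draftModels)
  expect_false(any(nov$gene_id %in% ann_ids))
  expect_true(all(nov$contig %in% names(tf$sim$draftContigs)))
  # absent genes have no draft contig at all
  expect_true(all(is.na(genes$contig[genes$role == "g5"])))
  # mis-split genes carry 2-3 adjacent models partitioning their exons
  ms <- genes[genes$role == "missplit", ]
  for (g in ms$gene_id) {
    parts <- grep(paste0("^", g, "\\.p"), ann_ids, value = TRUE)
    expect_gte(length(parts), 2L)
    expect_lte(length(parts), 3L)
  }
})

test_that("read generator honours chimera and error settings", {
  cfg0 <- simConfig(seed = 3, n_true_genes = 6, n_clr_reads = 15,
                    chimera_rate = 1, truncation_rate = 0)
  sim <- simulateGenome(cfg0)
  clr <- simulateClrReads(cfg0, sim)
  expect_true(all(clr$read_table$is_chimera))

  # per_base_error = 0: each pass equals the template insert
  cfg1 <- simConfig(seed = 3, n_true_genes = 6, n_clr_reads = 15,
                    per_base_error = 0, chimera_rate = 0,
                    truncation_rate = 0)
  clr1 <- simulateClrReads(cfg1, simulateGenome(cfg1))
  tt <- clr1$read_table
  tx <- simulateGenome(cfg1)$truth$transcripts
  pr <- isoPrimers()
  i <- which(tt$n_passes >= 2)[1]
  insert <- paste0(pr["p5"], tx$sequence[tx$tx_id == tt$tx_id[i]],
                   strrep("A", cfg1$polya_length),
                   IsoScan:::.revcomp_chr(pr["p3"]))
  clrseq <- as.character(clr1$reads[[i]])
  expect_equal(substr(clrseq, 1, nchar(insert)), insert)
  # pass count determines CLR length
  expect_equal(nchar(clrseq),
               unname(tt$n_passes[i] * nchar(insert) +
                        (tt$n_passes[i] - 1L) * nchar(pr["adapter"])))
})

test_that("short reads come only from stage-present transcripts and span junctions", {
  tf <- tiny_sim()
  pres <- tf$sim$truth$stage_presence
  for (s in seq_along(tf$short)) {
    src <- sub("^S[0-9]+_", "", names(tf$short[[s]]))
    src <- sub("_[0-9]+$", "", src)
    expect_true(all(pres[unique(src), s]))
  }
  # tiling guarantees junction-spanning reads for every expressed
  # multi-exon transcript (checked by exhaustive positional enumeration)
  short_t <- simulateShortReads(tf$cfg, tf$sim, tiling_step = 25L)
  tx <- tf$sim$truth$transcripts
  ex <- tf$sim$truth$exons
  L <- tf$cfg$short_read_length
  for (s in 1:2) {
    reads <- short_t[[s]]
    src <- sub("_[0-9]+$", "", sub("^S[0-9]+_", "", names(reads)))
    for (t in unique(src)) {
      ne <- sum(ex$tx_id == t)
      if (ne < 2L) next
      txlen <- tx$length[tx$tx_id == t]
      # enumerate: with step 25 and read length 101, every junction >= 8 nt
      # from the read edge is spanned by construction
      expect_gte(sum(src == t), floor((txlen - L) / 25))
    }
  }
  # zero depth -> empty libraries
  cfg0 <- simConfig(seed = 5, n_true_genes = 5, short_read_depth = 0)
  s0 <- simulateShortReads(cfg0, simulateGenome(cfg0))
  expect_true(all(vapply(s0, length, 0L) == 0L))
})

test_that("family generator plants diverged alleles and a premature stop", {
  fam <- simulateFamilyReads(seed = 2, n_alleles = 6, divergence = 0.03,
                             reads_per_allele = 5, error_rate = 0,
                             stop_codon_index = 100L)
  al <- as.character(fam$alleles)
  for (i in 1:5) for (j in (i + 1):6) {
    d <- mean(strsplit(al[i], "")[[1]] != strsplit(al[j], "")[[1]])
    expect_gte(d, 0.03)
  }
  # planted TAG at the stated codon of allele 1
  p <- fam$orf_start + 3L * (100L - 1L)
  expect_equal(unname(substr(al[1], p, p + 2L)), "TAG")
  expect_equal(length(fam$reads), 30L)
})
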