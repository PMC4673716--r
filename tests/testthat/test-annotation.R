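## small synthetic locus shared by the filtering tests: three reads at one
## locus with nested junction chains
.mk_hq_input <- function(support = 5L) {
  b_full <- cbind(qstart = c(1L, 101L, 201L), qend = c(100L, 200L, 300L),
                  tstart = c(1L, 201L, 401L), tend = c(100L, 300L, 500L))
  b_trunc <- cbind(qstart = c(1L, 101L), qend = c(100L, 200L),
                   tstart = c(201L, 401L), tend = c(300L, 500L))
  tab <- rbind(
    aln_row("full", "c1", 100, 100, read_length = 300L, blocks = b_full),
    aln_row("trunc", "c1", 100, 100, read_length = 200L, blocks = b_trunc),
    aln_row("full2", "c1", 100, 100, read_length = 300L, blocks = b_full))
  aln <- SplicedAlignments(tab)
  groups <- data.frame(read_id = c("full", "trunc", "full2"),
                       group = "G1", strand = "+",
                       stringsAsFactors = FALSE)
  js <- data.frame(contig = "c1", donor = c(101L, 301L),
                   acceptor = c(200L, 400L), support_count = support)
  list(groups = groups, aln = aln, js = js)
}

test_that("5'-truncated reads (strict chain suffixes) are removed", {
  x <- .mk_hq_input()
  hq <- filterHighQuality(x$groups, x$aln, x$js)
  expect_true("trunc" %in% hq$removed_5prime_truncated)
  expect_setequal(hq$kept, c("full", "full2"))
})

test_that("unsupported singletons are removed, supported ones kept", {
  x <- .mk_hq_input(support = 0L)
  # make 'full' unique (drop full2) so it is a singleton chain
  tab <- alignmentTable(x$aln)
  aln1 <- SplicedAlignments(tab[tab$read_id == "full", , drop = FALSE])
  g1 <- x$groups[x$groups$read_id == "full", , drop = FALSE]
  hq0 <- filterHighQuality(g1, aln1, x$js)   # zero junction support
  expect_true("full" %in% hq0$removed_unsupported_singletons)
  x2 <- .mk_hq_input(support = 3L)
  hq1 <- filterHighQuality(g1, aln1, x2$js)
  expect_true("full" %in% hq1$kept)
})

test_that("locus assignment clusters by exonic overlap on one strand", {
  b1 <- cbind(qstart = 1L, qend = 200L, tstart = 101L, tend = 300L)
  b2 <- cbind(qstart = 1L, qend = 200L, tstart = 251L, tend = 450L)
  b3 <- cbind(qstart = 1L, qend = 200L, tstart = 401L, tend = 600L)
  b4 <- cbind(qstart = 1L, qend = 200L, tstart = 2001L, tend = 2200L)
  tab <- rbind(
    aln_row("a", "c1", 100, 100, 200L, blocks = b1),
    aln_row("b", "c1", 100, 100, 200L, blocks = b2),
    aln_row("c", "c1", 100, 100, 200L, blocks = b3),
    aln_row("d", "c1", 100, 100, 200L, blocks = b4),
    aln_row("e", "c1", 100, 100, 200L, strand = "-", blocks = b1))
  groups <- data.frame(read_id = c("a", "b", "c", "d", "e"), group = "G1",
                       strand = c("+", "+", "+", "+", "-"),
                       stringsAsFactors = FALSE)
  aln <- SplicedAlignments(tab)
  js <- data.frame(contig = character(0), donor = integer(0),
                   acceptor = integer(0), support_count = integer(0))
  # models: one gene overlapping the a-b-c cluster
  models <- IsoScan:::.models_from_table(data.frame(
    gene_id = "g1", transcript_id = "g1.m1", contig = "c1",
    start = 101L, end = 600L, strand = "+", stringsAsFactors = FALSE))
  hq <- list(kept = c("a", "b", "c", "d", "e"),
             read_info = filterHighQuality(groups, aln, js)$read_info)
  loci <- assignLoci(hq, models)
  tabl <- loci$loci
  # transitive single-linkage: a-b-c form one cluster; d separate; e on the
  # opposite strand separate
  expect_equal(nrow(tabl), 3L)
  big <- tabl[tabl$n_reads == 3L, ]
  expect_equal(big$status, "EXTANT")
  expect_equal(sort(tabl$n_reads), c(1L, 1L, 3L))
  nov <- tabl[tabl$status == "NOVEL", ]
  expect_equal(nrow(nov), 2L)
  expect_true(all(nov$contig_has_other_models))
  # histogram bins
  expect_equal(unname(loci$histogram$counts),
               c(2L, 1L, 0L, 0L))
})

test_that("contig bridges obey the 600-bp end rule", {
  # two contigs, gene halves ending 100 bp from the facing ends
  mk_case <- function(dist_b) {
    cl <- c(cA = 2000L, cB = 2000L)
    bA <- cbind(qstart = 1L, qend = 500L, tstart = 1400L, tend = 1900L)
    bB <- cbind(qstart = 501L, qend = 1000L, tstart = dist_b + 1L,
                tend = dist_b + 500L)
    tab <- rbind(aln_row("r", "cA", 50, 100, 1000L, blocks = bA),
                 aln_row("r", "cB", 50, 100, 1000L, blocks = bB))
    groups <- data.frame(read_id = "r", group = "G3", strand = "+",
                         stringsAsFactors = FALSE)
    ort <- SplicedAlignments(aln_row("r", "ort1", 100, 98, 1000L))
    detectContigBridges(groups, SplicedAlignments(tab), ort, cl)
  }
  br <- mk_case(100L)
  expect_equal(nrow(br), 1L)
  expect_equal(br$end_distance_a, 100)   # 2000 - 1900
  expect_equal(br$end_distance_b, 100)
  expect_true(br$ortholog_contiguous)
  # a segment 900 bp from the contig end is not a bridge
  expect_equal(nrow(mk_case(900L)), 0L)
})

test_that("bridges on planted split genes are recovered with ortholog contiguity", {
  tf <- tiny_sim(); tm <- tiny_mapped()
  g3ids <- tm$groups$read_id[tm$groups$group == "G3"]
  expect_gt(length(g3ids), 0L)
  ort_genome <- do.call(c, unname(tf$sim$orthologGenome))
  ort_aln <- toySplicedAlign(flncSequences(tm$fl$flnc)[g3ids], ort_genome)
  br <- detectContigBridges(tm$groups, tm$aln, ort_aln,
                            setNames(Biostrings::nchar(tf$sim$draftContigs),
                                     names(tf$sim$draftContigs)))
  tt <- tf$clr$read_table
  true_g3 <- intersect(g3ids, tt$read_id[tt$group %in% "G3"])
  expect_equal(mean(true_g3 %in% br$read_id), 1)
  expect_true(all(br$ortholog_contiguous[br$read_id %in% true_g3]))
})

test_that("ortholog rescue applies the strict 90/90 rule", {
  set.seed(41)
  gene <- rand_dna(800)
  reads <- Biostrings::DNAStringSet(c(
    hit = gene,
    diverged = IsoScan:::.mutate(gene, 0.15)))
  gs <- list(Au = Biostrings::DNAStringSet(c(gene1 = gene)))
  res <- rescueUnmapped(reads, gs)
  m <- res$matches
  expect_true(m$rescued[m$read_id == "hit"])
  expect_false(m$rescued[m$read_id == "diverged"])   # ~85 % identity
  expect_equal(unname(res$counts["Au"]), 1L)
  expect_error(rescueUnmapped(reads, list(Au = Biostrings::DNAStringSet())),
               "empty gene set")
})

test_that("ORF completeness uses genomic containment of the cDNA codons", {
  set.seed(43)
  # cDNA with a clean ORF aligned over one exon
  orf_seq <- IsoScan:::.plant_orf(rand_dna(900))
  cdna <- orf_seq$seq
  genome_seq <- paste0(rand_dna(100), cdna, rand_dna(100))
  b_cdna <- cbind(qstart = 1L, qend = 900L, tstart = 101L, tend = 1000L)
  cdna_aln <- SplicedAlignments(aln_row("cd1", "c1", 100, 100, 900L,
                                        blocks = b_cdna))
  # read 1 spans the whole ORF, read 2 starts 30 nt past the start codon
  b_full <- cbind(qstart = 1L, qend = 900L, tstart = 101L, tend = 1000L)
  start_codon_genomic <- 100L + orf_seq$orf_start
  b_part <- cbind(qstart = 1L, qend = 800L,
                  tstart = start_codon_genomic + 30L,
                  tend = start_codon_genomic + 829L)
  reads <- rbind(aln_row("full", "c1", 100, 100, 900L, blocks = b_full),
                 aln_row("part", "c1", 100, 100, 800L, blocks = b_part))
  est <- estimateOrfCompleteness(SplicedAlignments(reads), cdna_aln,
                                 Biostrings::DNAStringSet(c(cd1 = cdna)))
  tab <- est$table
  expect_true(tab$complete[tab$read_id == "full"])
  expect_false(tab$complete[tab$read_id == "part"])
  expect_equal(est$n_total, 2L)
  expect_equal(est$percent, 50.0)
})

test_that("completeness report arithmetic matches the printed convention", {
  # percentage to one decimal, e.g. 21326 / 28599 -> 74.6
  expect_equal(derivePercentage(21326, 28599, 1), 74.6)
})
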