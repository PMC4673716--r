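## build a filterHighQuality-shaped input directly from alignment rows
.mk_iso_input <- function(tab, strands = NULL) {
  ids <- tab$read_id
  groups <- data.frame(read_id = ids, group = "G1",
                       strand = if (is.null(strands)) "+" else strands,
                       stringsAsFactors = FALSE)
  aln <- SplicedAlignments(tab)
  js <- data.frame(contig = "c1", donor = c(101L, 301L, 301L),
                   acceptor = c(200L, 400L, 404L), support_count = 5L)
  hq <- filterHighQuality(groups, aln, js)
  models <- IsoScan:::.models_from_table(data.frame(
    gene_id = "g1", transcript_id = "g1.m1", contig = "c1",
    start = c(1L, 201L, 401L), end = c(100L, 300L, 500L), strand = "+",
    stringsAsFactors = FALSE))
  loci <- assignLoci(hq, models)
  list(hq = hq, loci = loci, aln = aln, models = models)
}

test_that("reads collapse by identical junction chain", {
  b_chain <- function(acc2) cbind(
    qstart = c(1L, 101L, 201L), qend = c(100L, 200L, 300L),
    tstart = c(1L, 201L, acc2 + 1L), tend = c(100L, 300L, acc2 + 100L))
  tab <- rbind(
    # two reads with identical chains but different 5' extents
    aln_row("r1", "c1", 100, 100, 300L, blocks = b_chain(400L)),
    aln_row("r2", "c1", 100, 100, 300L, blocks = {
      b <- b_chain(400L); b[1, "tstart"] <- 21L; b[1, "qend"] <- 80L
      b[1, "qstart"] <- 1L; b[2, ] <- c(81L, 180L, 201L, 300L)
      b[3, ] <- c(181L, 280L, 401L, 500L); b
    }),
    # one read whose last acceptor differs by 4 nt
    aln_row("r3", "c1", 100, 100, 300L, blocks = b_chain(404L)))
  x <- .mk_iso_input(tab)
  iso <- collapseIsoforms(x$hq, x$loci, x$aln, x$models)
  expect_equal(nrow(iso), 2L)    # one different junction = a new isoform
  expect_setequal(iso$n_supporting_reads, c(2L, 1L))
  # conservation: supports sum to the number of kept reads
  expect_equal(sum(iso$n_supporting_reads), length(x$hq$kept))
  # the representative is the longest read
  big <- iso[iso$n_supporting_reads == 2L, ]
  expect_equal(big$representative_read, "r1")
  # KNOWN status: the chain matching the annotated model
  expect_equal(big$status, "KNOWN")
  expect_equal(iso$status[iso$n_supporting_reads == 1L],
               "NOVEL_AT_KNOWN_LOCUS")
})

test_that("single-exon reads collapse to one isoform per locus", {
  b1 <- cbind(qstart = 1L, qend = 400L, tstart = 101L, tend = 500L)
  tab <- do.call(rbind, lapply(1:5, function(i)
    aln_row(paste0("s", i), "c1", 100, 100, 400L, blocks = b1)))
  x <- .mk_iso_input(tab)
  iso <- collapseIsoforms(x$hq, x$loci, x$aln, x$models)
  expect_equal(nrow(iso), 1L)
  expect_equal(iso$n_supporting_reads, 5L)
  expect_equal(iso$chain, "")
})

test_that("collapsing the representatives returns the same isoform set", {
  tm <- tiny_mapped(); tf <- tiny_sim()
  ev_js <- data.frame(contig = character(0), donor = integer(0),
                      acceptor = integer(0), support_count = integer(0))
  hq <- filterHighQuality(tm$groups, tm$aln, ev_js)
  loci <- assignLoci(hq, tf$sim$draftModels)
  iso <- collapseIsoforms(hq, loci, tm$aln, tf$sim$draftModels)
  # rerun on representatives only
  reps <- iso$representative_read
  hq2 <- hq
  hq2$kept <- intersect(hq$kept, reps)
  loci2 <- assignLoci(hq2, tf$sim$draftModels)
  iso2 <- collapseIsoforms(hq2, loci2, tm$aln, tf$sim$draftModels)
  expect_equal(nrow(iso2), nrow(iso))
  expect_setequal(paste(iso2$contig, sort_chain(iso2$chain)),
                  paste(iso$contig, sort_chain(iso$chain)))
})

test_that("recovered junction chains equal the planted chains", {
  tm <- tiny_mapped(); tf <- tiny_sim()
  ev_js <- data.frame(contig = character(0), donor = integer(0),
                      acceptor = integer(0), support_count = integer(0))
  hq <- filterHighQuality(tm$groups, tm$aln, ev_js)
  loci <- assignLoci(hq, tf$sim$draftModels)
  iso <- collapseIsoforms(hq, loci, tm$aln, tf$sim$draftModels)
  tc <- truth_chains(tf$sim)
  multi <- iso[nzchar(iso$chain) & iso$n_supporting_reads >= 2L, ]
  got <- paste(multi$contig, sort_chain(multi$chain))
  want <- paste(tc$contig, tc$chain)
  expect_equal(mean(got %in% want), 1)
})

test_that("length statistics and support histogram match printed conventions", {
  st <- transcriptLengthStats(novel = c(575, 4537, 2187),
                              known = c(671, 4636, 1857))
  expect_equal(unname(st$novel["min"]), 575)
  expect_equal(unname(st$novel["max"]), 4537)
  # the published means differ by 45
  st2 <- transcriptLengthStats(novel = rep(2433, 3), known = rep(2388, 3))
  expect_equal(st2$mean_difference, 45)
  expect_equal(unname(transcriptLengthStats(c(100), c(100))$novel["mean"]),
               100)
  expect_error(transcriptLengthStats(numeric(0), c(1)), "empty")

  h <- locusSupportHistogram(c(3, 5, 7, 150))
  expect_equal(unname(h$counts), c(0L, 3L, 0L, 1L))
  expect_equal(unname(h$percent["2-10"]), 75)
  # inclusive upper edge: a count of 10 falls in the 2-10 bin
  expect_equal(unname(locusSupportHistogram(c(10))$counts["2-10"]), 1L)
  expect_equal(unname(locusSupportHistogram(rep(2, 8))$percent["2-10"]), 100)
})
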