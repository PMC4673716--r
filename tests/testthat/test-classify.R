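## genome with a canonical intron so multi-exon strands resolve to "+"
.mk_genome <- function() {
  set.seed(31)
  Biostrings::DNAStringSet(c(
    c1 = rand_dna(3000), c2 = rand_dna(3000), c3 = rand_dna(3000)))
}

test_that("the group cascade reproduces the published band definitions", {
  genome <- .mk_genome()
  tab <- rbind(
    aln_row("u1", "c1", 95, 96),                      # unique high -> G1
    aln_row("m1", "c1", 92, 94), aln_row("m1", "c2", 92, 94),  # tied -> G2
    aln_row("p1", "c1", 45, 95), aln_row("p1", "c2", 40, 95),  # partial -> G3
    aln_row("q1", "c1", 40, 70),                      # low quality -> G4
    aln_row("b1", "c1", 85, 95))                      # band gap -> catch-all
  aln <- SplicedAlignments(tab)
  gr <- classifyReadGroups(aln, genome,
                           read_ids = c("u1", "m1", "p1", "q1", "b1", "n1"))
  g <- setNames(gr$group, gr$read_id)
  expect_equal(unname(g["u1"]), "G1")
  expect_equal(unname(g["m1"]), "G2")
  expect_equal(unname(g["p1"]), "G3")
  expect_equal(unname(g["q1"]), "G4")
  expect_equal(unname(g["b1"]), "G4")   # significant but unclassified
  expect_equal(unname(g["n1"]), "G5")   # no alignment at all
  # ">90" for G1 is strict: exactly 90 does not qualify
  gr90 <- classifyReadGroups(SplicedAlignments(aln_row("e", "c1", 90, 95)),
                             genome, read_ids = "e")
  expect_equal(gr90$group, "G4")
})

test_that("classification partitions all reads and ignores input order", {
  tm <- tiny_mapped()
  tf <- tiny_sim()
  gr <- tm$groups
  ids <- flncInfo(tm$fl$flnc)$id
  expect_equal(nrow(gr), length(ids))
  expect_equal(sum(table(gr$group)), nrow(gr))
  # order independence
  ids <- flncInfo(tm$fl$flnc)$id
  gr2 <- classifyReadGroups(tm$aln, tf$sim$draftContigs,
                            read_ids = rev(ids))
  expect_equal(gr2[order(gr2$read_id), "group"],
               gr[order(gr$read_id), "group"])
})

test_that("planted groups are recovered exactly on error-free reads", {
  tm <- tiny_mapped(); tf <- tiny_sim()
  tt <- tf$clr$read_table
  m <- merge(tm$groups, tt[, c("read_id", "group")], by = "read_id",
             suffixes = c("", "_true"))
  m <- m[!is.na(m$group_true) & m$group != "UNDETERMINED", ]
  expect_equal(mean(m$group == m$group_true), 1)
})

test_that("multi-mapping patterns follow the three published categories", {
  genome <- .mk_genome()
  tab <- rbind(
    aln_row("homeo", "1AL_1", 95, 95), aln_row("homeo", "1DL_2", 95, 95),
    aln_row("para", "2BL_1", 95, 95), aln_row("para", "2BL_2", 95, 95),
    aln_row("para", "2BS_3", 95, 95),
    aln_row("mixed", "3AL_1", 95, 95), aln_row("mixed", "3AL_2", 95, 95),
    aln_row("mixed", "3DS_3", 95, 95))
  names(genome) <- c("x", "y", "z")
  gr <- classifyReadGroups(SplicedAlignments(tab), genome)
  sub <- contigSubgenomeMap(unique(tab$contig))
  pat <- g2PatternAnalysis(gr, sub)
  p <- setNames(pat$pattern, pat$read_id)
  expect_equal(unname(p["homeo"]), "ONE_BEST_PER_SUBGENOME")
  expect_equal(unname(p["para"]), "MULTI_WITHIN_ONE_SUBGENOME")
  expect_equal(unname(p["mixed"]), "MULTI_ACROSS_SUBGENOMES")
  # unknown subgenome contig is flagged with a warning
  tab2 <- rbind(aln_row("u", "weird_1", 95, 95),
                aln_row("u", "weird_2", 95, 95))
  gr2 <- classifyReadGroups(SplicedAlignments(tab2), genome)
  expect_warning(pat2 <- g2PatternAnalysis(gr2,
                                           contigSubgenomeMap(
                                             unique(tab2$contig))),
                 "unknown")
  expect_equal(pat2$pattern, "UNKNOWN_SUBGENOME")
})

test_that("junction extraction reads strand-adjusted motifs from the genome", {
  left <- rand_dna(100, seed = 35); right <- rand_dna(100)
  mk <- function(intron) Biostrings::DNAStringSet(c(
    c1 = paste0(left, intron, right)))
  b <- cbind(qstart = c(1L, 101L), qend = c(100L, 200L),
             tstart = c(1L, 181L), tend = c(100L, 280L))
  aln <- SplicedAlignments(aln_row("r", "c1", 100, 100,
                                   read_length = 200L, blocks = b))
  j1 <- extractJunctions(aln, mk(paste0("GT", rand_dna(76), "AG")))
  expect_equal(j1$motif, "GT-AG")
  expect_equal(j1$strand, "+")
  expect_equal(j1$donor, 101L)
  expect_equal(j1$acceptor, 180L)
  # minus-strand gene: genome shows CT..AC, motif is GT-AG after adjustment
  j2 <- extractJunctions(aln, mk(paste0("CT", rand_dna(76), "AC")))
  expect_equal(j2$motif, "GT-AG")
  expect_equal(j2$strand, "-")
  # non-canonical
  j3 <- extractJunctions(aln, mk(paste0("TT", rand_dna(76), "AG")))
  expect_equal(j3$motif, "other")
  # a genomic gap below min_intron is not a junction
  b2 <- b; b2[2, "tstart"] <- 121L; b2[2, "tend"] <- 220L
  aln2 <- SplicedAlignments(aln_row("r", "c1", 100, 100,
                                    read_length = 200L, blocks = b2))
  expect_equal(nrow(extractJunctions(aln2, mk(rand_dna(80)))), 0L)
})

test_that("junction validation requires exact coordinate matches", {
  lj <- data.frame(read_id = "r", contig = "c1", donor = 101L,
                   acceptor = 180L, strand = "+", motif = "GT-AG")
  sj <- data.frame(contig = "c1", donor = 101L, acceptor = 180L,
                   strand = "+", support_count = 5L)
  v <- validateJunctions(lj, sj)
  expect_true(v$junctions$supported)
  expect_equal(v$supported_fraction, 1)
  # donor off by one nucleotide -> unsupported
  sj2 <- sj; sj2$donor <- 102L
  expect_false(validateJunctions(lj, sj2)$junctions$supported)
  # zero support count does not validate
  sj3 <- sj; sj3$support_count <- 0L
  expect_false(validateJunctions(lj, sj3)$junctions$supported)
})
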