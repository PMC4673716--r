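test_that("RPKM follows exon_reads / (millions mapped x exon kb)", {
  expect_equal(computeRpkm(1000, 1e7, 2000), 50)
  expect_equal(computeRpkm(0, 1e7, 2000), 0)
  expect_error(computeRpkm(10, 1e6, 0), "zero exon length")
  expect_error(computeRpkm(10, 0, 1000), "empty library")
  # linearity: doubling reads doubles RPKM exactly
  set.seed(51)
  for (i in 1:20) {
    n <- sample(1:5000, 1); lib <- sample(1e5:1e7, 1)
    len <- sample(200:5000, 1)
    expect_equal(computeRpkm(2 * n, lib, len), 2 * computeRpkm(n, lib, len))
    # hand computation on random fixtures
    expect_equal(computeRpkm(n, lib, len), n / ((lib / 1e6) * (len / 1e3)))
  }
})

test_that("expressed calling uses a strict RPKM > 1 rule", {
  ev <- list(stages = list(
    S1 = list(gene_counts = c(gA = 10L, gB = 20L), library_size = 1e4,
              junction_support = numeric(0))))
  # gA: 10 / (0.01 x 1) = 1000; tune lengths so gB sits exactly at 1
  glen <- c(gA = 1000, gB = 2e6)
  # gB rpkm = 20 / (0.01 * 2000) = 1 exactly -> NOT expressed
  res <- callExpressedGenes(ev, glen)
  expect_equal(res$expressed$S1, "gA")
  expect_equal(res$rpkm$S1$rpkm[res$rpkm$S1$gene_id == "gB"], 1)
  # just above the threshold counts
  glen2 <- c(gA = 1000, gB = 2e6 * 0.99)
  expect_setequal(callExpressedGenes(ev, glen2)$expressed$S1, c("gA", "gB"))
})

test_that("isoform presence uses isoform-specific junctions only", {
  iso <- data.frame(
    transcript_id = c("t1", "t2"), locus_id = "L1", contig = "c1",
    strand = "+", chain = c("101-200;301-400", "101-200"),
    n_supporting_reads = c(5L, 3L), stringsAsFactors = FALSE)
  ev <- list(stages = list(
    S1 = list(junction_support = c(`c1:101-200` = 10, `c1:301-400` = 4)),
    S2 = list(junction_support = c(`c1:101-200` = 8))))
  pres <- isoformPresence(iso, ev)
  # t1's specific junction (301-400) is covered at S1 only
  p1 <- pres[pres$transcript_id == "t1", ]
  expect_equal(p1$present[p1$stage == "S1"], TRUE)
  expect_equal(p1$present[p1$stage == "S2"], FALSE)
  # t2 has no specific junction (its only junction is shared): unresolvable
  expect_true("t2" %in% attr(pres, "unresolvable"))
  expect_false("t2" %in% pres$transcript_id)
  # two isoforms with identical chains are both unresolvable
  iso2 <- iso; iso2$chain <- "101-200"
  pres2 <- isoformPresence(iso2, ev)
  expect_setequal(attr(pres2, "unresolvable"), c("t1", "t2"))
})

test_that("presence is monotone in short-read depth", {
  iso <- data.frame(transcript_id = "t1", locus_id = "L1", contig = "c1",
                    strand = "+", chain = "101-200",
                    n_supporting_reads = 2L, stringsAsFactors = FALSE)
  for (n in c(1, 3, 50)) {
    ev <- list(stages = list(S1 = list(
      junction_support = c(`c1:101-200` = n))))
    expect_true(isoformPresence(iso, ev)$present)
  }
  ev0 <- list(stages = list(S1 = list(junction_support = numeric(0))))
  expect_false(isoformPresence(iso, ev0)$present)
})

test_that("differential calling flags any non-constant presence vector", {
  iso <- data.frame(
    transcript_id = c("a1", "b1"), locus_id = "L1", contig = "c1",
    strand = "+", chain = c("1-2;3-4", "1-2;5-6"),
    n_supporting_reads = c(9L, 4L), stringsAsFactors = FALSE)
  mk_pres <- function(va, vb) {
    stages <- paste0("S", 1:4)
    rbind(
      data.frame(transcript_id = "a1", locus_id = "L1", stage = stages,
                 supporting_reads = as.integer(va), present = va > 0),
      data.frame(transcript_id = "b1", locus_id = "L1", stage = stages,
                 supporting_reads = as.integer(vb), present = vb > 0))
  }
  # isoform a present S1-S3 only, b throughout -> differential
  d1 <- differentialIsoformTable(mk_pres(c(2, 2, 2, 0), c(1, 1, 1, 1)), iso)
  expect_true(d1$differential)
  # labels follow descending support: a1 (9 reads) is "a"
  expect_match(d1$patterns, "^a:1110")
  # all isoforms present at all stages -> not differential
  d2 <- differentialIsoformTable(mk_pres(rep(1, 4), rep(2, 4)), iso)
  expect_false(d2$differential)
})

test_that("short-read evidence assigns reads to unique loci only", {
  set.seed(52)
  exon1 <- rand_dna(300); exon2 <- rand_dna(300)
  intron <- paste0("GT", rand_dna(100), "AG")
  genome <- Biostrings::DNAStringSet(c(
    c1 = paste0(rand_dna(50), exon1, intron, exon2, rand_dna(50)),
    c2 = paste0(rand_dna(50), exon1, intron, exon2, rand_dna(50))))
  # identical transcripts at two loci: nothing can be assigned uniquely
  tx <- data.frame(transcript_id = c("tA", "tB"), gene_id = c("gA", "gB"),
                   contig = c("c1", "c2"), strand = "+",
                   stringsAsFactors = FALSE)
  b <- cbind(qstart = 0L, qend = 0L, tstart = c(51L, 455L),
             tend = c(350L, 754L))
  tx$blocks <- list(b, b)
  txseq <- paste0(exon1, exon2)
  reads <- Biostrings::DNAStringSet(vapply(seq(1, 400, by = 40), function(s)
    substr(txseq, s, s + 100), ""))
  names(reads) <- sprintf("r%02d", seq_along(reads))
  ev <- shortReadEvidence(list(S1 = reads), tx, genome)
  expect_equal(length(ev$stages$S1$gene_counts), 0L)
  expect_equal(ev$stages$S1$library_size, 0L)
  expect_equal(sum(ev$stages$S1$junction_support), 0L)
  # a locus-unique transcript gets both counts and junction support
  tx1 <- tx[1, ]; tx1$blocks <- list(b)
  ev1 <- shortReadEvidence(list(S1 = reads), tx1, genome)
  expect_gt(ev1$stages$S1$gene_counts[["gA"]], 0L)
  expect_gt(sum(ev1$stages$S1$junction_support), 0L)
  # the junction key is genomic: donor right after exon 1
  expect_true("c1:351-454" %in% names(ev1$stages$S1$junction_support))
})
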