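test_that("coverage and identity follow the stated formulas", {
  ci <- computeCoverageIdentity(matches = 940, mismatches = 10, indels = 0,
                                aligned_read_bases = 950, read_length = 1000)
  expect_equal(unname(ci["coverage"]), 95.0)
  expect_equal(round(unname(ci["identity"]), 2), 98.95)
  # full-length perfect
  ci2 <- computeCoverageIdentity(1000, 0, 0, 1000, 1000)
  expect_equal(unname(ci2), c(100, 100))
  # 300/1000 aligned: the partial-mapping band floor
  ci3 <- computeCoverageIdentity(300, 0, 0, 300, 1000)
  expect_equal(unname(ci3["coverage"]), 30.0)
  expect_error(computeCoverageIdentity(0, 0, 0, 0, 100), "zero aligned")
})

test_that("the spliced aligner recovers planted exon/intron structure exactly", {
  set.seed(21)
  exon1 <- rand_dna(300); exon2 <- rand_dna(250)
  intron <- paste0("GT", rand_dna(500), "AG")
  genome <- Biostrings::DNAStringSet(c(
    chr = paste0(rand_dna(200), exon1, intron, exon2, rand_dna(200))))
  read <- Biostrings::DNAStringSet(c(r1 = paste0(exon1, exon2)))
  aln <- toySplicedAlign(read, genome)
  tb <- alignmentTable(aln)
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$coverage, 100)
  expect_equal(tb$identity, 100)
  b <- tb$blocks[[1]]
  expect_equal(nrow(b), 2L)
  # intron exactly at the planted coordinates
  expect_equal(unname(b[1, "tend"]), 200L + 300L)
  expect_equal(unname(b[2, "tstart"]), 200L + 300L + 504L + 1L)
  # a random sequence aligns nowhere
  rnd <- Biostrings::DNAStringSet(c(r2 = rand_dna(500)))
  expect_equal(length(toySplicedAlign(rnd, genome)), 0L)
})

test_that("homoeologous copies are reported at their planted divergence", {
  set.seed(22)
  gene <- rand_dna(900)
  copyB <- IsoScan:::.mutate(gene, 0.03)
  genome <- Biostrings::DNAStringSet(c(
    cA = paste0(rand_dna(150), gene, rand_dna(150)),
    cB = paste0(rand_dna(150), copyB, rand_dna(150))))
  aln <- toySplicedAlign(Biostrings::DNAStringSet(c(r = gene)), genome)
  tb <- alignmentTable(aln)
  expect_equal(sort(unique(tb$contig)), c("cA", "cB"))
  idA <- tb$identity[tb$contig == "cA"][1]
  idB <- tb$identity[tb$contig == "cB"][1]
  expect_equal(idA, 100)
  # oracle: the true divergence of the planted copy
  true_div <- mean(strsplit(gene, "")[[1]] != strsplit(copyB, "")[[1]])
  expect_equal(idB, 100 * (1 - true_div), tolerance = 0.5)
})

test_that("toy aligner identity matches a full DP oracle on single-exon genes", {
  set.seed(23)
  checked <- 0L
  for (i in 1:14) {
    gene <- rand_dna(180)
    # errors only in the interior so both aligners see identical extents
    # (the seed-and-extend aligner clips noisy read ends, the forced
    # end-to-end oracle cannot)
    read <- paste0(substr(gene, 1, 15),
                   IsoScan:::inject_errors_cpp(substr(gene, 16, 165), 0.05),
                   substr(gene, 166, 180))
    genome <- Biostrings::DNAStringSet(c(g = paste0(rand_dna(100), gene,
                                                    rand_dna(100))))
    tb <- alignmentTable(toySplicedAlign(
      Biostrings::DNAStringSet(c(r = read)), genome))
    if (!nrow(tb) || tb$coverage[1] < 99.5) next
    checked <- checked + 1L
    # oracle: Biostrings global-local alignment of the read to the region
    pa <- Biostrings::pairwiseAlignment(read, as.character(genome[[1]]),
                                        type = "global-local")
    ref_id <- 100 * Biostrings::nmatch(pa) /
      (Biostrings::nmatch(pa) + Biostrings::nmismatch(pa) +
         Biostrings::nindel(pa)@insertion[, "WidthSum"] +
         Biostrings::nindel(pa)@deletion[, "WidthSum"])
    expect_lt(abs(tb$identity[1] - ref_id), 1.0)
  }
  expect_gte(checked, 6L)
})

test_that("best-locus selection maximises score and flags ties", {
  tab <- rbind(aln_row("r", "c1", 95, 100), aln_row("r", "c2", 85, 94.4))
  sel <- selectBestLocus(tab)
  expect_equal(sel$best$contig, "c1")
  expect_false(sel$ambiguous)
  # near-tied scores are ambiguous
  tab2 <- rbind(aln_row("r", "c1", 95, 100), aln_row("r", "c2", 94.95, 100))
  expect_true(selectBestLocus(tab2)$ambiguous)
  # a single alignment is itself
  sel3 <- selectBestLocus(aln_row("r", "c1", 50, 80))
  expect_equal(sel3$best$contig, "c1")
  expect_false(sel3$ambiguous)
  expect_error(selectBestLocus(SplicedAlignments()), "empty")
})

test_that("strand follows canonical intron motifs, orientation otherwise", {
  set.seed(24)
  gseq <- paste0(rand_dna(100), "GT", rand_dna(60), "AG", rand_dna(100))
  genome <- Biostrings::DNAStringSet(c(c1 = gseq))
  # intron spans 101..164; exons 51..100 and 165..214
  b <- cbind(qstart = c(1L, 51L), qend = c(50L, 100L),
             tstart = c(51L, 165L), tend = c(100L, 214L))
  aln <- aln_row("r", "c1", 100, 100, read_length = 100L, blocks = b)
  expect_equal(determineStrand(aln, genome), "+")
  # minus-strand gene: genome shows CT..AC
  gseq2 <- paste0(rand_dna(100), "CT", rand_dna(60), "AC", rand_dna(100))
  expect_equal(determineStrand(aln, Biostrings::DNAStringSet(c(c1 = gseq2))),
               "-")
  # single-exon read with near-equal scores in both orientations
  aln1 <- aln_row("r", "c1", 100, 100, read_length = 100L)
  expect_equal(determineStrand(aln1, genome,
                               both_orient_scores = c(100, 99.95)), "?")
  expect_equal(determineStrand(aln1, genome,
                               both_orient_scores = c(100, 80)), "+")
})
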