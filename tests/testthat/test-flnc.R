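pr <- isoPrimers()

mk_insert <- function(cdna, polya = 30L) {
  paste0(pr["p5"], cdna, strrep("A", polya), IsoScan:::.revcomp_chr(pr["p3"]))
}

test_that("subread splitting cuts at adapters and filters fragments", {
  set.seed(1)
  insert <- mk_insert(rand_dna(500))
  rc <- IsoScan:::.revcomp_chr(insert)
  clr <- paste0(insert, pr["adapter"], rc, pr["adapter"], insert)
  sr <- splitSubreads(clr, pr["adapter"], flncConfig())
  expect_length(sr, 3L)           # 2 adapters -> 3 passes
  # antisense passes are flipped onto the first fragment's orientation
  expect_equal(sr[[2]], insert)
  # no adapter: the whole read is one subread (single-pass path)
  expect_length(splitSubreads(insert, pr["adapter"], flncConfig()), 1L)
  # fragments below mini_length are dropped
  clr2 <- paste0(substr(insert, 1, 40), pr["adapter"], insert)
  expect_length(splitSubreads(clr2, pr["adapter"], flncConfig()), 1L)
  # read score below threshold drops everything
  expect_length(splitSubreads(clr, pr["adapter"], flncConfig(),
                              read_score = 0.5), 0L)
})

test_that("consensus is a per-column majority with ties kept from the reference", {
  s <- rand_dna(300, seed = 2)
  cc <- buildCcs(c(s, s, s))
  expect_equal(cc$sequence, s)
  expect_equal(cc$predicted_accuracy, 1.0)
  expect_equal(cc$type, "I")
  # one disagreeing base at one column: majority wins
  s2 <- s
  substr(s2, 150, 150) <- if (substr(s, 150, 150) == "A") "C" else "A"
  cc2 <- buildCcs(c(s, s2, s))
  expect_equal(cc2$sequence, s)
  expect_equal(cc2$n_passes, 3L)
  # a single subread passes through as type II
  cc3 <- buildCcs(s)
  expect_equal(cc3$type, "II")
  expect_equal(cc3$sequence, s)
})

test_that("consensus of noisy subreads beats any single subread", {
  # independent oracle: simulate templates, measure identities directly
  set.seed(33)
  pidf <- function(a, b) {
    r <- IsoScan:::banded_global_cpp(a, b, 120L)
    r$nmatch / (r$nmatch + r$nmismatch + r$nins + r$ndel)
  }
  wins <- 0L
  for (i in 1:40) {
    tmpl <- rand_dna(500)
    subs <- vapply(1:5, function(j)
      IsoScan:::inject_errors_cpp(tmpl, 0.10), "")
    cc <- buildCcs(subs)
    cons_id <- pidf(cc$sequence, tmpl)
    sub_ids <- vapply(subs, pidf, 0, b = tmpl)
    if (cons_id > max(sub_ids)) wins <- wins + 1L
  }
  expect_gte(wins, 36L)   # consensus better than every subread nearly always
})

test_that("FLNC classification requires both primers, a poly(A) tail and no internal primer", {
  set.seed(4)
  # end the insert on non-A bases so the poly(A) run has a sharp boundary
  cdna <- paste0(rand_dna(597), "GTC")
  ok <- classifyFlnc(mk_insert(cdna, polya = 30L))
  expect_equal(ok$status, "flnc")
  expect_equal(ok$sequence, cdna)
  expect_equal(ok$polya_len, 30L)
  # orientation is rederived: a reverse-complemented insert still classifies
  flip <- classifyFlnc(IsoScan:::.revcomp_chr(mk_insert(cdna)))
  expect_equal(flip$status, "flnc")
  expect_equal(flip$sequence, cdna)
  # missing poly(A)
  nopa <- paste0(pr["p5"], cdna, IsoScan:::.revcomp_chr(pr["p3"]))
  expect_equal(classifyFlnc(nopa)$status, "no_polya")
  # missing primers
  expect_equal(classifyFlnc(paste0(cdna, strrep("A", 30),
                                   IsoScan:::.revcomp_chr(pr["p3"])))$status,
               "no_5p")
  expect_equal(classifyFlnc(paste0(pr["p5"], cdna,
                                   strrep("A", 30)))$status, "no_3p")
  # internal primer copy -> chimeric
  chim <- mk_insert(paste0(cdna, pr["p5"], rand_dna(400)))
  expect_equal(classifyFlnc(chim)$status, "chimeric")
  # poly(A) below min_polya
  short_pa <- classifyFlnc(mk_insert(cdna, polya = 10L))
  expect_equal(short_pa$status, "no_polya")
})

test_that("the CLR -> FLNC stage conserves counts and recovers planted reads", {
  tf <- tiny_sim()
  tm <- tiny_mapped()
  st <- tm$fl$stats
  # partition: every CLR is FLNC, rejected or filtered
  expect_equal(st$n_flnc + sum(st$rejections), st$n_clr)
  expect_equal(st$n_flnc, st$n_flnc_type_I + st$n_flnc_type_II)
  # on error-free input, recovery of planted FLNC reads is exact
  tt <- tf$clr$read_table
  predv <- flncInfo(tm$fl$flnc)$id
  truth_pos <- tt$read_id[tt$flnc_eligible]
  expect_equal(mean(predv %in% truth_pos), 1)
  expect_equal(mean(truth_pos %in% predv), 1)
  # no FLNC read retains primer or poly(A) sequence
  seqs <- as.character(flncSequences(tm$fl$flnc))
  expect_false(any(grepl(pr["p5"], seqs, fixed = TRUE)))
  expect_false(any(grepl(strrep("A", 25), substr(seqs,
                                                 nchar(seqs) - 30,
                                                 nchar(seqs)), fixed = TRUE)))
})

test_that("pileup correction fixes covered errors and respects the depth floor", {
  set.seed(9)
  tmpl <- rand_dna(400)
  reads <- Biostrings::DNAStringSet(vapply(seq(1, 300, by = 10), function(s)
    substr(tmpl, s, s + 100), ""))
  names(reads) <- sprintf("sr%02d", seq_along(reads))
  mut <- tmpl
  substr(mut, 200, 200) <- if (substr(tmpl, 200, 200) == "G") "T" else "G"
  fs <- FlncSet(Biostrings::DNAStringSet(c(x = mut)),
                data.frame(id = "x", polya_len = 30L, had_5p_primer = TRUE,
                           had_3p_primer = TRUE, source_type = "I",
                           n_passes = 3L, corrected = FALSE))
  co <- correctWithShortReads(fs, reads)
  expect_equal(as.character(flncSequences(co$flnc)[[1]]), tmpl)
  # with depth 2 at the error site and min depth 3, nothing changes
  reads2 <- reads[c(TRUE, rep(FALSE, 4))]
  co2 <- correctWithShortReads(fs, reads2,
                               config = flncConfig(correction_min_depth = 30L))
  expect_equal(as.character(flncSequences(co2$flnc)[[1]]), mut)
  # no coverage at all: read passes through unchanged, not flagged corrected
  co3 <- correctWithShortReads(fs, Biostrings::DNAStringSet(
    setNames(rand_dna(101), "unrelated")))
  expect_equal(as.character(flncSequences(co3$flnc)[[1]]), mut)
  expect_false(flncInfo(co3$flnc)$corrected[1])
})
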