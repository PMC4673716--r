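fam_fixture <- function() memo("fam_fixture", function() {
  simulateFamilyReads(seed = 6, n_alleles = 6, divergence = 0.03,
                      reads_per_allele = 12, error_rate = 0.005,
                      stop_codon_index = 110L)
})

test_that("family search finds near-identical reads and rejects others", {
  fam <- fam_fixture()
  hits <- searchFamily(fam$reads[1:10], fam$query)
  expect_equal(nrow(hits), 10L)
  expect_true(all(hits$identity > 93))
  # an unrelated sequence yields no hit
  none <- searchFamily(Biostrings::DNAStringSet(c(x = rand_dna(900, 61))),
                       fam$query)
  expect_equal(nrow(none), 0L)
  expect_error(searchFamily(fam$reads[1:2], Biostrings::DNAStringSet()),
               "empty query")
})

test_that("reads matching two paralogous queries go to the higher-scoring one", {
  set.seed(62)
  qa <- rand_dna(600)
  qb <- IsoScan:::.mutate(qa, 0.05)
  queries <- Biostrings::DNAStringSet(c(parA = qa, parB = qb))
  reads <- Biostrings::DNAStringSet(c(r1 = qa))
  h <- searchFamily(reads, queries)
  expect_equal(h$query_id, "parA")
})

test_that("ORF checking distinguishes intact, disrupted and partial reads", {
  fam <- fam_fixture()
  q <- as.character(fam$query[[1]])
  intact <- as.character(fam$alleles[["allele02"]])
  expect_equal(checkOrf(intact, q)$status, "COMPLETE_INTACT")
  # the planted premature stop is reported at its codon index
  dis <- checkOrf(as.character(fam$alleles[["allele01"]]), q)
  expect_equal(dis$status, "COMPLETE_DISRUPTED")
  expect_equal(dis$premature_stop_pos, 110L)
  # truncation ahead of the start codon
  trunc <- substr(intact, fam$orf_start + 30L, nchar(intact))
  expect_equal(checkOrf(trunc, q)$status, "PARTIAL")
})

test_that("non-redundant clustering separates alleles and absorbs read error", {
  fam <- fam_fixture()
  hits <- searchFamily(fam$reads, fam$query,
                       families = setNames("HMW-GS", names(fam$query)))
  dd <- dedupeFamilyTranscripts(hits, fam$reads, fam$query)
  expect_equal(nrow(dd$clusters), 6L)    # exactly the planted alleles
  expect_equal(sum(dd$clusters$orf_status == "COMPLETE_DISRUPTED"), 1L)
  expect_equal(dd$clusters$premature_stop_pos[
    dd$clusters$orf_status == "COMPLETE_DISRUPTED"], 110L)
  # summary arithmetic: complete / positive, one decimal
  tot <- dd$summary$totals
  expect_equal(tot$complete_orf_percent,
               round(100 * tot$n_complete_reads / tot$n_positive_reads, 1))
  # published convention check: 1211 of 1577 -> 76.8
  expect_equal(derivePercentage(1211, 1577, 1), 76.8)
})
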