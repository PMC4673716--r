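test_that("percentages are rounded half-up at reporting precision", {
  expect_equal(derivePercentage(134204, 197709, 2), 67.88)
  expect_equal(derivePercentage(21326, 28599, 1), 74.6)
  expect_equal(derivePercentage(0, 100, 1), 0)
  expect_message(v <- derivePercentage(5, 0), "zero denominator")
  expect_true(is.na(v))
  # half-up, not banker's rounding
  expect_equal(derivePercentage(125, 1000, 1), 12.5)
  expect_equal(derivePercentage(1205, 10000, 1), 12.1)
})

test_that("every derived figure and identity follows from the raw counts", {
  s <- deriveSummary(wheatStudyCounts())
  d <- s$derived
  expect_equal(d$flnc_total, 197709)
  expect_equal(d$direction_resolved, 186765)
  expect_equal(d$g1_percent_of_flnc, 67.88)
  expect_equal(d$hq_total, 91881)
  expect_equal(d$loci_total, 16188)
  expect_equal(d$transcripts_total, 22768)
  expect_equal(d$novel_transcripts, 9591)
  expect_equal(d$transcripts_confirming, 13177)
  expect_equal(d$orf_complete_percent, 74.6)
  expect_equal(d$novel_loci_annotated_percent, 80.4)
  expect_equal(d$mean_length_difference, 45)
  expect_equal(d$g2_retained, 15049)
  expect_equal(d$gluten_transcripts_total, 72)
  expect_equal(d$gluten_complete_percent, 76.8)
  expect_equal(d$differential_genes, 6030)
  expect_true(all(s$checks))
})

test_that("a tiny pipeline run satisfies the additive report identities", {
  tf <- tiny_sim()
  out <- withr::local_tempdir()
  run <- suppressWarnings(suppressMessages(
    runPipeline(tf$cfg, outdir = out, correct = FALSE)))
  r <- run$report
  expect_equal(r$flnc_total, r$flnc_type_I + r$flnc_type_II)
  expect_equal(sum(r$groups), r$flnc_total)
  expect_equal(r$hq_total, unname(r$groups["G1"]) - r$hq_excluded)
  expect_equal(r$transcripts_total,
               r$transcripts_known + r$transcripts_new_at_known +
                 r$transcripts_at_novel)
  # resuming re-reads completed stages and reproduces the report
  run2 <- suppressWarnings(suppressMessages(
    runPipeline(tf$cfg, outdir = out, resume = TRUE, correct = FALSE)))
  expect_identical(run2$report[names(run2$report) != "correction"],
                   r[names(r) != "correction"])
})
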