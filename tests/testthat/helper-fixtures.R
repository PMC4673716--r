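## Shared fixtures: built once per test run and memoised.  All fixtures are
## generated in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fun) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, fun(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## a small, error-free simulated study shared by several test files
tiny_sim <- function() memo("tiny_sim", function() {
  cfg <- simConfig(seed = 42, n_true_genes = 14, n_clr_reads = 150,
                   per_base_error = 0, n_subgenomes = 3)
  sim <- simulateGenome(cfg)
  clr <- simulateClrReads(cfg, sim)
  short <- simulateShortReads(cfg, sim)
  list(cfg = cfg, sim = sim, clr = clr, short = short)
})

## FLNC + alignments for the tiny study
tiny_mapped <- function() memo("tiny_mapped", function() {
  tf <- tiny_sim()
  fl <- runFlnc(tf$clr$reads, tf$clr$scores)
  aln <- toySplicedAlign(flncSequences(fl$flnc), tf$sim$draftContigs)
  groups <- classifyReadGroups(aln, tf$sim$draftContigs,
                               read_ids = flncInfo(fl$flnc)$id)
  list(fl = fl, aln = aln, groups = groups)
})

## hand-built single-row alignment table (for classification unit tests)
aln_row <- function(read_id, contig, cov, id, read_length = 1000L,
                    strand = "+", blocks = NULL) {
  if (is.null(blocks)) {
    alen <- as.integer(round(read_length * cov / 100))
    blocks <- cbind(qstart = 1L, qend = alen, tstart = 101L,
                    tend = 100L + alen)
  }
  r <- data.frame(read_id = read_id, contig = contig, strand = strand,
                  read_length = read_length,
                  matches = 0L, mismatches = 0L, indels = 0L,
                  coverage = cov, identity = id, score = cov * id / 100,
                  stringsAsFactors = FALSE)
  r$matches <- as.integer(round(sum(blocks[, 2] - blocks[, 1] + 1) *
                                  id / 100))
  r$mismatches <- as.integer(sum(blocks[, 2] - blocks[, 1] + 1)) - r$matches
  r$blocks <- list(blocks)
  r
}

## junction chains of the planted transcripts, one row per single-contig
## multi-exon transcript (sorted-chain keys)
truth_chains <- function(sim) {
  ex <- sim$truth$exons
  ex <- ex[!is.na(ex$contig), ]
  ex <- ex[order(ex$tx_id, ex$start), ]
  out <- lapply(split(seq_len(nrow(ex)), ex$tx_id), function(ii) {
    if (length(ii) < 2L) return(NULL)
    cc <- unique(ex$contig[ii])
    if (length(cc) != 1L) return(NULL)
    d <- ex$end[ii][-length(ii)] + 1L
    a <- ex$start[ii][-1L] - 1L
    data.frame(tx_id = ex$tx_id[ii][1], contig = cc,
               chain = paste(sort(sprintf("%d-%d", d, a)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

sort_chain <- function(v) {
  vapply(strsplit(v, ";", fixed = TRUE), function(x)
    paste(sort(x), collapse = ";"), "")
}
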