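---
title: "Full-length transcript analysis for fragmented polyploid draft genomes"
author: "IsoScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-length transcript analysis for fragmented polyploid draft genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hexaploid wheat carries three homoeologous subgenomes (A, B, D) whose gene
copies are typically about 97 % identical, and its draft genome assemblies
are fragmented: single genes can be split across contigs, adjacent gene
models can be artifacts of one transcription unit, and many loci are missing
from the annotation or from the assembly altogether.  Short-read
transcriptomics struggles exactly where these problems matter: reads from
near-identical homoeologs cross-map, and assembled transcript tags cannot
prove full-length gene structure.

Single-molecule full-length cDNA sequencing addresses this by reading whole
transcripts in one pass.  IsoScan implements the complete analysis path for
such data against a fragmented draft genome: from raw multi-pass continuous
long reads (CLRs), through full-length non-chimeric (FLNC) read extraction
and hybrid error correction, splice-aware mapping and read-group
partitioning, to annotation improvement, an isoform catalogue, stage-wise
expression calls and a targeted gene-family search.  A synthetic-data
generator with planted ground truth makes every one of these stages testable
at desk scale.

## From raw reads to FLNC reads

A CLR is a multi-pass read of one circular library molecule: alternating
sense/antisense copies of the insert `5' primer + cDNA + poly(A) + 3'
primer`, separated by a hairpin adapter.  `splitSubreads()` cuts the CLR at
approximate adapter occurrences and orients all passes by shared k-mer
content.  The adapter edit budget (30 % of its length) is deliberately more
permissive than the primer budget (20 %): an undetected adapter merges two
passes into a double-length fragment that can poison the consensus, whereas
a spurious extra cut merely yields two usable fragments.  For the same
reason the consensus reference is the longest *typical* fragment: fragments
longer than 1.6 times the median are treated as adapter-miss artifacts and
excluded.

`buildCcs()` aligns all subreads to the reference with a banded global
aligner and takes a per-column majority (ties keep the reference base);
insertions need a strict majority of identical insertion strings.  This is a
deliberate simplification of a full partial-order-alignment consensus:
adequate at the 2-12 pass depths simulated here, and an order of magnitude
cheaper.  Reads with a single pass go through uncorrected ("type II"); with
two or more passes they become consensus ("type I") reads.

`classifyFlnc()` then demands all three structural signals: the 5' primer at
the start, the 3' primer at the end preceded by a poly(A) run of at least 20
bases (10 % non-A tolerated -- the length and impurity are our choices; the
source criterion is only a "distinct" tail), and no interior primer
occurrence (which marks a chimera of two inserts).  Orientation is
re-derived rather than trusted, so reverse-complemented consensus reads
classify identically.

### Hybrid error correction

Short reads are anchored on each FLNC read by exact 15-mers, banded-aligned,
and piled up; positions with depth of at least 3 are revised.  Three guards
matter in a polyploid, and all three were arrived at the hard way:

* **Best-placement filtering.** A short read that aligns almost as well to
  several long reads votes only on placements within one mismatch of its
  best.  This keeps homoeologous reads out of each other's pileups whenever
  the read's own copy is represented.
* **Quality-weighted voting with a super-majority.** A placement with *m*
  edits votes with weight 1/(1+m²), and a base is only changed when 75 % of
  the weighted pileup agrees.  Without this, a homoeolog expressed ten times
  higher than its sister would overwrite the sister's alleles wherever the
  sister's own long-read coverage is missing.
* **Anchored vote trimming.** Votes start and end at a run of at least six
  consecutive matches, because a padded-window global alignment scatters
  stray one-base matches near its edges, and converts edge-proximal
  mismatches into deletions.

At a residual error of a fraction of a percent the correction is essentially
neutral (it can still lose a few hundredths of a percent to homoeolog
columns with no same-copy coverage -- an information-theoretic limit, not an
implementation one); at the raw 12 % single-pass error it recovers several
percentage points of identity on top of the consensus.

## Mapping and the five read groups

The toy spliced aligner follows the standard seed-chain-extend recipe:
exact 15-mer seeds (repeat-masked above 32 genome occurrences), a
minimap2-style colinear chaining DP, block refinement with banded alignment
of inter-seed gaps, and x-drop end extension.  Genomic gaps of at least 40
bases become introns; their boundaries are slid (up to 6 bases, where the
exon edge repeats the intron edge) onto canonical splice motifs, GT..AG
first, then GC..AG and AT..AC.  Without intron sliding about a quarter of
junctions land one base off whenever the exon boundary base repeats -- the
classic junction-wobble artifact.

Coverage is the aligned fraction of the read; identity is
`matches/(matches+mismatches+indels)` with indels counted in gap bases (the
source never defines its identity; we adopt the aligner-style match
fraction).  A read's best locus maximises `coverage x identity/100`; a score
difference below 0.1 is a tie.

Classification applies the published band definitions as an ordered
cascade, because the five groups exactly exhaust the published read totals
-- which is only possible if some rule catches everything left over:

0. alignment direction unresolvable (motif conflict, or a single-exon read
   scoring equally in both orientations): set aside;
1. unique best alignment, coverage and identity both above 90: **G1**;
2. two or more tied best alignments at distinct loci, both metrics at 90 or
   above (an "or" mode is available; the published wording is ambiguous):
   **G2**;
3. partial alignments (identity at least 90, coverage 30-80) on two or more
   contigs: **G3**;
4. anything still unclassified with identity at least 40 and coverage at
   least 30 -- including unique alignments falling in the gaps the published
   bands leave, such as coverage 85 at identity 95: **G4**;
5. everything else: **G5**.

## Annotation improvement

High-quality filtering removes reads missing 5' exons (junction chain a
strict suffix of a same-locus read's chain, 5' end downstream) and
unsupported singletons (sole read of its chain with no short-read junction
support; single-exon singletons need overlapping short-read coverage).
Locus clustering is single-linkage exonic overlap of at least one base on
one contig and strand -- the source never defines its clustering rule, and
one base is the least arbitrary choice.

Cross-contig (G3) reads become contig bridges when two draft contigs carry
segments with identity above 90 whose inner ends lie within 600 bases of
the facing contig ends and which together cover at least 80 % of the read.
At toy scale every split read also produces echo alignments on the sister
homoeologs, so the bridge detector selects the dominant non-overlapping
segment pair by score rather than demanding literally "exactly two"
contigs.  A bridge is ortholog-validated when the read maps contiguously
(one colinear alignment, coverage at least 80) onto the diploid-relative
reference.  The generator plants split genes with at most 100 bases of the
breakpoint intron retained on each contig -- what assembly fragmentation
actually leaves behind -- so planted bridges respect the 600-base rule by
construction.

Transcripts overlapping the exons of two or three annotated models on one
contig at above 90/90 are merge candidates; they are VALIDATED when they
also map at 80/80 or better into an orthologous region annotated with
exactly one gene.  Unmapped and low-quality reads are rescued against the
relatives' transcript sets under the strict above-90/90 rule.  ORF
completeness is estimated by genomic-span containment: a read at a locus
shared with a reference full-length cDNA is complete when its aligned span
contains both the cDNA ORF's start- and stop-codon genomic positions --
robust to residual read errors because no read-level translation is
involved.

## Isoforms and expression

Two multi-exon transcripts are different isoforms when they differ in at
least one junction; chains are compared exactly, since junction wobble is
already removed by motif sliding.  Single-exon reads collapse to one
isoform per locus and strand (the source leaves this case undefined).  A
discovered isoform is KNOWN only on exact chain equality with an annotated
transcript.

Short reads are matched exactly against the spliced transcript sequences
extracted from the genome for the discovered catalogue (the genome, not the
noisy reads, supplies the sequence).  Junction support and gene counts use
uniquely mapping reads only, at the locus level: roughly `0.97^101`, about
5 %, of homoeologous 101-base reads are error-free in a window where the
copies happen to agree, and would otherwise donate phantom junction support
across subgenomes.  A gene is expressed at a stage when its RPKM --
`exon reads / (millions of uniquely mapped reads x exon kilobases)` --
strictly exceeds 1.  Isoform presence per stage requires at least one read
on an isoform-specific junction; isoforms without a specific junction
(including all single-exon isoforms) are unresolvable and excluded from the
presence/absence differential table, which flags a gene when any resolvable
isoform's presence vector varies across stages.

Presence recovery is only *decodable* where the catalogue is complete: if a
sister homoeolog's isoform is missing from the catalogue, its reads have no
home and can leak through the unique-mapper filter.  The acceptance checks
therefore condition exactness on family-completeness; on those families
recovery at tiling depth is exact.

## Gene-family search

The storage-protein families (HMW-GS, LMW-GS, gliadins) are single-exon,
highly similar multigene families.  Reads are matched to family queries by
k-mer-prefiltered banded alignment (80 % identity and query coverage, our
defaults; the source's search settings are unstated).  Clustering into
non-redundant transcripts is two-stage: greedy assignment at a read-to-read
threshold of 97.5 % (both reads carry the residual-error budget, so the
pairwise bound is twice as loose as the allele-level 99 %), then each
cluster representative is polished by majority consensus and all reads are
reassigned against the polished alleles at 98.5 %.  Reassignment empties
the occasional noise-seeded singleton cluster, so six planted alleles
yield exactly six clusters.  ORF status -- intact, disrupted (with the
premature-stop codon index), or partial -- is judged on the polished
consensus, because residual indels in individual reads shift reading
frames and would flag noise as disruption.

## The synthetic study

The generator emulates the study conditions end to end: 200 gene families
by default, three subgenomes at 3 % pairwise homoeolog divergence
(substitution-only, so exon coordinates stay comparable across copies),
genes of 1-12 exons with 80-600-base exons and 60-2000-base introns so
transcripts land in the realistic 575-4600-base range (single-exon,
storage-protein-like genes are allowed up to 2400 bases), and GT-AG,
GC-AG, AT-AC intron motifs at 97.5/2/0.5 %.  Planted classes: 5 % of
families split across two contigs, 5 % mis-annotated as adjacent models,
10 % unannotated, 6 % with indistinguishable copies, 4 % partially and
divergently assembled, 3 % absent from the draft.  Identical-copy families
share one expression pattern across copies, because distinct per-copy
patterns would be unrecoverable from uniquely mapping reads by
construction.

Reads: 5000 CLRs with 1-12 passes (mean about 5.4, roughly 11 % single
pass -- calibrated to the subread-to-consensus ratios of real 2-kb
libraries on 120-minute movies), 12 % raw per-base error split 40:30:30
substitution:insertion:deletion (the source reports only post-hoc
identities, not an error spectrum), 2 % chimeras, 8 % 5'-truncated inserts,
5 % sub-threshold read scores, 30-base poly(A) tails.  Four stage libraries
of error-free 101-base reads at about 20x per expressed transcript;
`tiling_step` switches to deterministic tiling when exactness is being
tested.  Short reads are generated strand-forward (a stranded-protocol
simplification) and error-free -- their error processes are not what any
of the tested methods depends on.  5'-truncated reads from split or
partially assembled genes carry no planted mapping group: truncation moves
them between bands unpredictably (a read that loses the contig-A half of a
split gene becomes a clean unique mapper).

What passing these tests does *not* show about real data: no reference
bias, no systematic (homopolymer) error structure, no internal priming or
library artifacts beyond simple chimeras, flat quality values, and
substitution-only homoeolog divergence.  The generator is a decoding
test-bench, not a sequencing simulator.

## Problem sizes and numerical choices

The packaged checks run the full-size study (200 families, 5000 CLRs) for
the FLNC stage and the identity ladder, and a 60-family, 800-read
error-free study for the mapping, annotation, isoform and expression
checks; the gene-family check uses the stated six alleles at 100 reads
each.  The identity ladder is measured on a 150-read sample.  Internal
values keep full precision; percentages are rounded half-up only at
reporting time, to the one or two decimals the published tables use.
Alignment bands adapt to sequence-length differences; ties in best-locus
selection are broken deterministically by contig name and genomic start.
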