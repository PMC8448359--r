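---
title: "Mapping plasmid insertion sites from low-coverage WGS: methods and design"
author: "plasmidSV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping plasmid insertion sites from low-coverage WGS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidSV)
```

## The problem

Forward-genetic screens in haploid microbes such as *Chlamydomonas
reinhardtii* generate thousands of insertional mutants by transforming a
linearized selectable plasmid into the genome. Finding the causative gene
behind each phenotype requires knowing where the plasmid landed and what
collateral damage (deletions, duplications, rearrangements) accompanied
the integration. Low-coverage whole-genome sequencing (~5-10x) of each
mutant is an economical way to do this at scale: paired-end reads in which
one mate maps to the plasmid contig and the other to a chromosome pinpoint
the junctions, and read pairs with aberrant orientation or spacing reveal
the associated structural variation.

plasmidSV implements the full analysis: discordant-pair insertion-site
calling, junction sizing, secondary (plasmid-unassociated) deletion
calling, gene-disruption annotation, population allele tables, and a
deterministic curation rule set for higher-confidence candidate genes. A
built-in simulator generates references, mutant genomes, reads and
truth-based alignments so every stage is testable end-to-end against known
ground truth.

## The evidence model

Alignments against a combined reference (nuclear chromosomes plus the
plasmid as an extra contig) are reduced to read pairs. A pair is
**discordant** iff its mates map to different contigs, or to the same
contig with non-facing orientation, or with an implied fragment length
outside `fragmentMean ± 3·fragmentSd`. Three partitions matter:

* **plasmid-paired** — one mate on the plasmid: direct insertion-junction
  evidence;
* **interchromosomal** and **non-facing intrachromosomal** — rearrangement
  evidence (genome-genome junctions);
* **facing pairs with long implied fragments** — deletion-spanning
  evidence, consumed by the deletion caller, deliberately *excluded* from
  rearrangement clustering (a long fragment-length outlier is not a
  rearrangement).

Chromosomal anchors are clustered by single linkage within a window of
`fragmentMean + 3·fragmentSd` (780 bp at the defaults), split by
chromosome, side (forward-strand anchors pointing toward higher
coordinates are *left* of a junction; reverse-strand anchors are *right*)
and partner class. Clusters need `minSupport = 2` pairs; the threshold is
exposed because at ~15x physical coverage of 600 bp fragments two pairs
balance sensitivity against stray noise. Alignments below `mapqMin = 20`
feed only the repeat-flank diagnosis, standing in for the judgment a
curator makes when one flank maps to a low-complexity region.

## Junctions: soft-clips first

Each site receives a junction estimate with an explicit evidence grade.
If at least one read is soft-clipped at a consistent coordinate (spread
<= 2 bp) on the junction side, the junction is the modal clip coordinate
with **uncertainty 0**; otherwise the innermost mate boundary is used with
uncertainty `fragmentMean − 2·readLength` (300 bp at defaults). This
hierarchy is what lets the caller report exact small gaps (a 4 bp or
10 bp deletion, a 7 bp target-site duplication) when clip evidence exists,
while honestly widening to a +/- 300 bp envelope when it does not. Gap
classification refuses to over-interpret: if either side is
discordant-only and |right − left| falls inside the combined uncertainty,
the gap class is `unknown` rather than a guessed perfect/deletion call.

Left and right plasmid sites on one chromosome are paired greedily by
junction distance, accepting signed gaps from `−duplicationCap` (1000 bp;
larger negative gaps are flagged for review because real target-site
duplications stay below 1 kb) up to `maxPairDistance` (200 kb, chosen
above the largest junction deletion the method is expected to see).
Distance ties break deterministically toward lower coordinates and are
flagged rather than silently resolved.

## Complex insertions, translocations, cofragments

A leftover plasmid site whose locus also anchors a genome-genome cluster
is linked into a **complex lesion** with its partner locus; chains are
followed transitively (a lesion may span several chromosomes; cycles are
closed, not errors). A lesion whose plasmid sites span two or more
chromosomes is a **translocation** — plasmid at one junction of a chimeric
chromosome pair — otherwise it is complex. Remaining leftover sites are
one-sided: `repeat_flank` when sub-mapq plasmid-paired anchors or repeat
mask occupy the missing flank, `no_discordant_reads` otherwise.

Co-inserted genome fragments are detected by three joint criteria:
discordant links from the insertion junction to a distal interval, mean
depth over that interval >= 1.6x the flanking baseline (the source locus
still exists, so the extra copy doubles its depth), and interval length
< 10 kb. All three are required; links with flat depth, or a depth ratio
of 1.05, yield no call.

## Secondary deletions

Deletions unassociated with the plasmid are called by three routes keyed
to size, then merged and partitioned by proximity (`slop` = 1 kb) to
insertion lesions:

| route | evidence label | size band | boundary accuracy |
|---|---|---|---|
| in-read deletion ops (>= 2 reads agreeing +/- 2 bp) | `gapped_read` | 20-100 bp | exact |
| facing pairs with implied length > mean + 5 sd, plus paired clip clusters | `spanning_pair` | ~100 bp-36 kb | exact when clip-refined |
| runs of depth <= 1 of length >= 500 bp, < 50% repeat overlap | `coverage_drop` | >= 500 bp | clip-refined when possible |

Two numerical choices deserve note. The spanning route requires implied
lengths beyond **5** standard deviations although discordance is defined
at 3: fragment-length outliers between 3 and 5 sd are common enough at
genome scale that they would otherwise seed false candidates, and the
100-180 bp deletions they could have caught are covered by clip pairing.
`maxDepth = 1` (not 0) tolerates stray mismapped reads at 7.44x. Runs
touching chromosome ends are discarded as edge artefacts. Read + coverage
agreement upgrades the evidence label to `both`. Detection is
coverage-limited by construction: recall at 3x is measurably below recall
at 7.44x, which the test suite verifies as a property rather than hiding.

## Annotation, allele tables, curation

Footprints follow the event taxonomy: a junction deletion contributes its
deleted interval; perfect and duplication insertions contribute junction
points only (a tandem micro-duplication deletes nothing); one-sided and
complex events contribute each mapped junction point. Coordinates are
0-based half-open internally and 1-based at every file boundary
(SAM/GFF3/TSV); a zero-length junction point at `p` intersects `[a, b)`
iff `a <= p < b`. A gene is affected iff a footprint intersects its gene
body — UTRs included, since insertions in 5'- and 3'-UTRs demonstrably
produce (partial) loss of function — with context assigned by the most
severe overlapped feature (whole-gene deletion > CDS exon > 5'-UTR >
3'-UTR > intron). Genes whose promoter alone is hit are not counted by
default; a configurable upstream window exists but is off, because
body-overlap is the defensible minimal rule.

Allele tables union insertion- and deletion-affected genes per gene with
distinct-mutant counting. Within groups of mutants whose lesions share
genes, disruption frequency (fraction of group members affecting the
gene) ranks candidates; the causative gene of a shared phenotype is
expected at frequency 1.

Curation mirrors a manual sweep as a fixed-order rule engine: (R1) a
simple-only mutant disrupting exactly one gene names it immediately; (R2)
a unique disruption-frequency maximum wins for every group member —
complex mutants may join groups, since a complex mutant sharing a single
gene with a deletion cluster is precisely the informative case; (R3)
otherwise flag scores (GreenCut2-style membership 2; keyword,
co-expression and each cross-library hit 1 each) pick a unique maximum;
(R4) positive-score ties report all tied genes; (R5) otherwise none.
After one pass, genes co-disrupted alongside R1/R2 winners are demoted
population-wide and decisions are re-evaluated exactly once — a single
sweep matches how such curation is actually done and guarantees
termination. The weights codify qualitative published practice, are
exposed in the call, and every firing is written to an audit trail;
fidelity to any particular hand-curated list is not claimed. A mutant
with all flag scores zero yields `none` rather than reporting an
uninformative all-gene tie.

## The simulator: what it emulates, and what it does not

The generator's defaults are the study conditions of a screen-scale
library: mean depth 7.44, 600 +/- 60 bp fragments, 2 x 150 bp reads, a
~5 kb plasmid, and an event mixture derived from observed frequencies —
67.5% two-sided with junction deletion, 5.2% with target-site duplication
(< 1 kb, log-uniform), 4.0% perfect, 2.5% one-sided at repeat flanks,
1.8% with a co-inserted 200-2000 bp fragment, 19% complex
(intra-/inter-chromosomal, 3% translocation), ~1.09 insertions per mutant
(1 + Poisson(0.09)), and 0.13 unassociated deletions per mutant spanning
20 bp-36 kb. Junction deletion sizes follow a two-component log-uniform
mixture (11-100 bp and 10-100 kb, equal weights) — the minimal model for
the observed bimodal spectrum. Repeat blocks are exact 1 kb internal
duplications covering `repeatFraction` of each chromosome; reads born in
them get mapping quality 0, which is how an aligner treats exact copies.
The plasmid is rejection-sampled to share no 31-mer with the chromosomes.

Alignments are emitted from truth through each mutant's segment map
rather than by re-running an aligner: junction-spanning reads are
soft-clipped at the breakpoint, colinear gaps <= 100 bp become in-read
deletion ops (the behaviour of a banded aligner at 150 bp reads), and
proper-pair flags follow the same concordance definition the caller uses.
An ingest adapter accepts real SAM/BAM with identical downstream
behaviour, so the emitter is a replaceable stand-in, not a hidden
assumption.

Deliberate non-goals of the simulator: sequencing errors beyond uniform
substitutions, indel errors, GC and coverage bias, adapter contamination,
chimeric artefacts, and real aligner quirks (multi-mapping heuristics,
mate rescue). Passing tests therefore demonstrate correctness of the
*calling logic* under clean mapping; they do not certify performance on
real libraries, where mapping artefacts add noise the thresholds here can
only approximate. Concatemer insertions are supported via a copy-number
knob but default to a single copy; no claim is made about real concatemer
frequency.

## Closed-form calculators

Saturation: the chance a library of *n* insertions hits a given gene is
`1 − exp(−n·L/G)` with *L* the average exon length per gene and *G* the
genome size — 58% for n = 60,000, L = 1,583 bp, G = 111 Mb. Linkage: with
~*n* zygospores per backcross and 2 antibiotic-resistant progeny per
zygospore tested on selective medium, zero recombinants bound the map
distance below `100/(2n)` cM — 0.5 cM, i.e. ~50 kb at 100 kb/cM. The
bound formula is this package's reconstruction of the underlying tetrad
arithmetic; it reproduces the printed pair and is documented as such.
Set overlaps use the hypergeometric upper tail (one-sided Fisher), with
the gene-universe size a required explicit argument rather than a hidden
default. Percentages round half-to-even.

## Problem sizes and determinism

The test and acceptance simulations run on a 3 x 500 kb genome with a
5 kb plasmid — large enough that windows, repeat blocks and 100 kb
deletions coexist without crowding, small enough that a 250-mutant
recovery trial completes in minutes. Recovery is scored against truth
tables: at 7.44x the caller attains >= 95% recall and precision on
two-sided insertions, recovers clip-evidenced gaps exactly, and
reproduces the bimodal deletion-size spectrum; secondary deletions reach
>= 90% recall over 20 bp-36 kb with size-exact gapped-read calls. Every
stochastic step takes an explicit seed and restores the caller's RNG
state; identical (configuration, seed) inputs give byte-identical FASTA,
FASTQ, SAM and TSV outputs.

## Known limitations

* One-sided "no discordant reads" cases are emitted when evidence is
  absent, but the simulator does not deliberately create them (they arise
  from stochastic coverage gaps, which clean simulation mostly avoids).
* Junctions without soft-clip coverage (a few percent at 7.44x) carry a
  +/- 300 bp envelope; small gaps there are reported `unknown`, never
  guessed.
* De novo assembly of rearranged junctions and base-level concatemer
  structure are out of scope; complex lesions report linked loci, not
  reconstructed sequence.
* The 100-180 bp deletion band relies on paired soft-clips alone and is
  the least sensitive part of the size spectrum at low coverage.
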