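---
title: "Annotating liver cis-regulatory elements and measuring their cross-species conservation"
author: "CREconserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating liver cis-regulatory elements and measuring their cross-species conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(CREconserve))
```

## The problem

Histone-modification ChIP-seq gives a practical route to annotating the
non-coding regulatory genome of a tissue: H3K4me3 marks promoters,
H3K27ac marks active regulatory chromatin, and their joint pattern
separates active promoters, poised promoters, distal enhancers, broad
H3K4me3 domains and super-enhancers. Once a liver regulatory map exists
for one species, the natural comparative question is how much of it is
shared with other mammals — and at which level: is the underlying DNA
still alignable (*sequence* conservation), and if so, does the
orthologous locus still carry the same regulatory mark in the same tissue
(*functional* conservation)?

CREconserve implements that whole analysis as a tested pipeline: peak
quality control, element classification, ROSE-style super-enhancer
calling, chain-based coordinate mapping with minimum-match semantics,
three-way conservation classification, chromatin-state overlay of
sequence-only conserved elements, expression linkage, and core
transcriptional regulatory circuitry (CRC) construction. Because the
real inputs are terabyte-scale alignments, the package ships a
synthetic-data generator that emulates every input with planted ground
truth, so each stage — and the pipeline end to end — is verifiable on a
desktop.

## Classification rules

The element definitions are deliberately simple threshold rules, applied
verbatim and tested at their boundaries:

* **Peak QC.** Narrow peaks with Poisson p > 0.01 and broad peaks with
  p > 0.1 are removed (boundary values are kept: the removal rule is
  strictly "greater than"). Surviving peaks must show two-fold
  enrichment, RPM~IP~ ≥ 2·RPM~Input~, *and* RPM~IP~ − RPM~Input~ > 1.
  RPM is reads per million against a declared library size carried in
  the coverage-track header, which keeps RPM well defined for sparse
  bedGraph tracks.
* **Promoters.** Every QC-passed H3K4me3 peak. Peaks overlapping an
  H3K27ac peak by ≥ 1 bp are *active* promoters; the rest are *poised*.
* **Enhancers.** H3K27ac peaks with zero overlap with any H3K4me3 peak
  and zero overlap with any TSS window (2.5 kb upstream to 1.5 kb
  downstream of a TSS, strand-aware). H3K27ac peaks failing the rule
  without being promoter-paired are kept in an `unclassified` report
  rather than dropped.
* **Broad domains.** H3K4me3 peaks overlapping a TSS window with
  original width strictly greater than 4 kb. Width is measured on the
  raw peak: the 2 kb standardized form would make the rule
  unsatisfiable.
* **Standardization.** Before cross-species mapping, every element
  becomes the 2 kb window centred on its summit, then passes the
  enrichment filter a second time. Windows running off a chromosome end
  are clipped and flagged, not dropped — dropping would silently bias
  telomeric elements.

The overlap predicate is ≥ 1 bp everywhere. That is the weakest reading
of "overlapping"/"outside of", and using one predicate uniformly keeps
the partition properties exact (active ∪ poised = promoters; enhancers
never touch a TSS window — both are asserted by re-scan in the tests).

## Super-enhancers

Stitching joins same-chromosome enhancers whose gap is ≤ 12,500 bp
(transitively), the ROSE default. The gap comparison is "≤" on the
number of intervening bases; the boundary is fixed and tested because
stitching implementations differ exactly there. Region signal is the sum
of input-subtracted RPM over *constituent intervals only* — stitched
gaps contribute nothing.

The cutoff is geometric: sort signals ascending, min–max scale ranks to
x ∈ [0,1] and signals to y ∈ [0,1], and take the index maximising
x − y. For a convex increasing curve this is the tangent point where the
scaled slope reaches 1 — the "hockey-stick" elbow. Ties break to the
highest index (fewest super-enhancers, the conservative choice), and
regions strictly above the cutoff signal are super-enhancers. A
brute-force scan over all indices serves as the oracle in the tests.

TSS-proximal exclusion before stitching exists but is off by default:
elements reaching this stage were already TSS-depleted by the enhancer
definition. Gene assignment offers two modes — all TSS inside the
stitched interval falling back to the single nearest
(`overlap_then_nearest`, the default) or nearest-only — because the
choice is genuinely open; distance ties break lexicographically by gene
id so results are permutation-stable.

## Chain mapping and conservation

Coordinate mapping re-implements the liftOver contract on UCSC chain
files: an interval maps iff its aligned bases lie on a single chain
(split hits are rejected, mirroring liftOver's default) and the aligned
fraction of the original width reaches `minMatch` (0.2, the value used
for cross-species element conversion). The target interval is the span
of the mapped bases; '-'-strand chains store target coordinates in
reverse-complement convention exactly as the format specifies, and the
mapper reflects them back to forward coordinates. The implementation is
block-arithmetic; the test oracle maps every base independently and must
agree exactly, including on gapped and reverse-strand chains.

Conservation is then three-way: unmapped elements are *un-conserved*;
mapped elements overlapping (≥ 1 bp) a target element of the same class
are *functionally conserved*; mapped elements without such an overlap
are *sequence-only conserved*. The match is class-aware (an enhancer
landing on a promoter is not functional conservation) and one-way;
a reciprocal-mapping check is deliberately out of scope since nothing in
the analysis requires it.

Sequence-only conserved elements are overlaid on per-tissue
chromatin-state segmentations: in each tissue an element takes the
category of the state segment with the largest overlap (single-valued by
construction; ties break to genome order), and counts as "regulatory
elsewhere" if any tissue gives an active-enhancer, weak-enhancer or
primary-DNase category. The element-by-tissue matrix is one-hot encoded
and clustered with standard k-means (k = 100, seeded, capped at the
number of distinct patterns) for display ordering.

## Expression linkage

Cross-species expression tables of one-to-one orthologs are quantile
normalized (every column receives the per-rank across-column mean; ties
get the mean of the tied ranks' reference values — limma's
implementation matches this definition exactly and is used directly).
Differential-expression calls consume per-gene statistics and apply the
thresholds |log2 fold| ≥ 2 (inclusive), p < 0.001 and FDR < 0.01 (both
strict); Benjamini–Hochberg FDR is computed on request when only
p-values are supplied. Group comparisons (active vs poised promoter
genes, super-enhancer-linked vs typical-enhancer-linked genes) use the
Wilcoxon rank-sum test: exact when the smaller group has ≤ 8
observations and no ties — which keeps it verifiable against full
enumeration — and the tie-corrected normal approximation otherwise.
Element–gene linkage is nearest-TSS by interval distance with
lexicographic tie-break.

## Core regulatory circuitry

CRC construction is simplified but structurally faithful: candidate TFs
are super-enhancer-assigned genes expressed at ≥ 1 TPM; a candidate
becomes a node iff its own motif hits its own super-enhancer constituent
sequences (auto-regulation); A → B edges come from motif hits of A in
B's constituents; circuitries are maximal cliques of the mutual graph,
enumerated exactly (Bron–Kerbosch; a 2^n subset scan is the test
oracle). Motif scanning is a log2-odds scan in bits over both strands
with N scored as background. The default hit threshold is 6 bits; this
replaces FIMO's p-value machinery, whose null calibration is out of
scope, and is configurable. Constituent sequences can be extended
±500 bp before scanning. Cross-species comparison intersects
clique-member names case-insensitively via one-to-one orthologous
naming.

## What the synthetic data emulates

`SyntheticConfig` fixes the study conditions; the generator derives
child seeds from one master seed by fixed offsets, so identical seeds
give byte-identical files and sub-generators stay decoupled.

* **Genome and genes** — chromosomes of equal length; non-overlapping
  genes on a per-chromosome grid with stranded TSS; log-normal TPM
  (meanlog 1.5, sdlog 1.2 — a realistically skewed bulk-tissue
  distribution) in two correlated replicates.
* **Peaks** — a configurable fraction of H3K4me3 peaks inside TSS
  windows (15% of them wide enough to be broad domains), the rest
  distal; H3K27ac split into TSS-distal enhancer-like peaks and
  promoter-overlapping peaks. Placement uses disjoint slots, which
  guarantees same-mark peaks never overlap and standardized 2 kb windows
  stay separated — the generator's contract with the chain planter.
  Active-promoter H3K27ac lands preferentially on better-expressed genes
  (sampling weight proportional to TPM), reproducing the
  active-above-poised expression ordering.
* **Signal** — enhancer RPM is Pareto(α = 1.5, minimum 5): heavy-tailed
  enough that a hockey-stick elbow always exists; promoter-scale peaks
  are log-normal around 10. 7% of peaks get failing p-values and 5% get
  weak enrichment, so the QC filters have real work. Coverage is written
  at 10 bp resolution with per-peak read totals equal to the recorded
  RPM against a fixed library size of 10^6; multiplicative noise
  (`noiseSd`, default 0.1) perturbs totals, and at `noiseSd = 0`
  recomputing RPM from coverage reproduces the records exactly.
* **Conservation** — per-element status is planted with exact counts at
  the configured fractions (0.30 functional / 0.55 sequence-only by
  default), functional status biased towards gene-proximal elements
  (exponential weight in distance rank) to reproduce the
  closer-to-genes signature. Chains are then *constructed around* the
  elements: un-conserved elements fall in alignment gaps, conserved ones
  inside blocks, indels are interleaved between elements, and the last
  chromosome's chain is emitted on the '-' target strand. Functional
  elements get a same-class target element at their image; a fifth of
  sequence-only elements get a different-class decoy.
* **States, PWMs, CRC** — per-tissue segmentations plant a configured
  fraction (0.782 by default, matching the reported share of
  sequence-only conserved enhancers active in some tissue) of elements
  as regulatory in ≥ 1 tissue, biased towards one primary tissue;
  PWMs are near-deterministic consensus matrices, so planted occurrences
  are retrievable by string match; the three-species CRC scenario plants
  an exact overlap structure (10 shared TFs, 16/8/8 specific).

What the generator does **not** emulate: realistic nucleotide
composition or mappability, read-level noise (coverage is an idealized
density), overlapping same-mark peaks, many-to-many orthology,
rearrangements beyond colinear indels and one whole-chromosome
inversion, and FIMO's motif-score null. Passing tests therefore
demonstrate that the *rules* are implemented correctly and that planted
structure is recovered at the stated tolerances — not that the pipeline
is robust to every artefact of real ChIP-seq data.

## Numerical choices and degenerate inputs

* All internal coordinates are 1-based closed GRanges; conversion to and
  from 0-based half-open formats (BED, narrowPeak, bedGraph, chain)
  happens only in the I/O layer.
* The elbow cutoff refuses fewer than 3 signals and returns zero
  super-enhancers with a warning when all signals are equal.
* k-means on the state matrix errors when k exceeds the number of
  distinct patterns and shortcuts k = n to singleton clusters.
* Ties: signal ranking breaks to genome order; gene assignment to
  lexicographic gene id; elbow to the highest index; state overlay to
  genome order. Every tie rule is deterministic, so reruns are
  byte-identical.
* broadPeak records have no summit; the interval midpoint is used.
* Empty TSS sets are a hard error in classification (the enhancer
  definition is undefined without TSS windows), and a gene-free
  reference yields empty annotation and expression tables.

## Problem sizes

The bundled demonstration (`runDemo`, seed 7) uses 2 × 6.5 Mb
chromosomes, 200 genes, 180 H3K4me3 and 500 H3K27ac peaks — chosen so
enhancer spacing (~30 kb) sits well above the 12.5 kb stitch distance
and the full run takes tens of seconds. The recovery analyses in the
test suite and acceptance script scale the coordinate-only simulations
up (4 × 9 Mb, 7,000 H3K27ac peaks) so that more than 5,000 standardized
enhancers are mapped, putting three binomial standard deviations of the
planted fractions inside ±0.02. Known limitation: at enhancer densities
approaching one per stitch distance, stitching merges most enhancers and
super-enhancer calls reflect cluster size more than planted signal —
the generator's defaults deliberately avoid that regime, and real
analyses should check the stitched-region size distribution.
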