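# CREconserve

Annotation and cross-species conservation analysis of liver
cis-regulatory elements from histone ChIP-seq.

## What it does

Two histone marks carry most of the information needed to annotate a
tissue's regulatory genome: H3K4me3 (promoters) and H3K27ac (active
regulatory chromatin). CREconserve turns peak calls and coverage tracks
for these marks into a classified element map and asks, element by
element, whether each one is conserved in another species — and at which
level:

* **Peak QC** — replicate concordance on 10 kb bins (Pearson r), Poisson
  p-value filters (narrow p ≤ 0.01, broad p ≤ 0.1), and the two-fold
  enrichment rule RPM_IP ≥ 2·RPM_Input with RPM_IP − RPM_Input > 1.
* **Element classification** — promoters (all H3K4me3 peaks), active vs
  poised promoters (± H3K27ac overlap), enhancers (H3K27ac free of
  H3K4me3 and outside every TSS window, −2.5 kb/+1.5 kb), broad H3K4me3
  domains (TSS-window-overlapping peaks wider than 4 kb), and 2 kb
  summit-centred standardization.
* **Super-enhancers** — ROSE-style stitching (≤ 12.5 kb gaps),
  input-subtracted signal over constituents, and the hockey-stick elbow:
  with ranks and signals min–max scaled to [0,1], the cutoff index
  maximises x − y (the point where the curve's slope reaches 1); regions
  strictly above it are super-enhancers.
* **Conservation** — chain-based interval mapping with liftOver
  minimum-match semantics (minMatch 0.2, split hits rejected,
  reverse-strand chains handled per the UCSC spec), then a three-way
  call: un-conserved (unmapped), sequence-only (mapped, no same-class
  target overlap), functional (mapped onto a same-class element).
  Distance-to-gene comparisons with a 100×4000 random control band and
  KS tests; chromatin-state overlay and k-means (k = 100) profiling of
  sequence-only conserved elements.
* **Expression linkage** — quantile normalization across species,
  DE threshold filtering (|log2FC| ≥ 2, p < 0.001, FDR < 0.01),
  TSS-flank (±1 kb) histone intensity, nearest-TSS gene linkage, and
  Wilcoxon rank-sum group comparisons (exact for small groups).
* **Core regulatory circuitry** — PWM log-odds scanning of
  super-enhancer constituents, auto-regulation-gated nodes, mutual-edge
  cliques (exact Bron–Kerbosch), and cross-species intersection of
  circuitry members.

Every input has a seeded synthetic generator with planted ground truth
(conservation fractions, Pareto-tailed enhancer signal, expression
shifts, CRC overlap), so the whole pipeline runs and is tested without
any external data.

## Worked example

```r
library(CREconserve)
res <- runDemo("demo_out", seed = 7)
```

The demo simulates a two-chromosome genome, runs every stage, and logs
per-stage survivor counts:

```
simulate: 180 H3K4me3 and 500 H3K27ac peaks on 2 chromosomes
qc: replicate r = 0.985; H3K4me3 180 -> 163 -> 131, H3K27ac 500 -> 464 -> 436 (p-value, enrichment filters)
annotate: 131 promoters (50 active, 81 poised), 354 enhancers, 21 broad domains, 32 unclassified H3K27ac
standardize: 354 of 354 enhancers pass the second-pass enrichment filter on 2 kb summit windows
superenhancer: 256 stitched regions, 11 super-enhancers (cutoff 54.106)
conserve: 106 functional, 195 sequence-only, 53 un-conserved (planted fractions 0.30 / 0.55, recovered 0.299 / 0.551)
conserve: functional vs sequence-only distance KS D = 0.381, p = 4.31e-09 (control: 100 draws of 354)
overlay: 148 / 195 sequence-only conserved enhancers regulatory in >= 1 tissue; k-means k = 52
express: 20 DEGs (10 up, 10 down) of 200 one2one orthologs
express: active > poised promoter expression p = 1.67e-07; SE-linked > typical-linked p = 0.00549 (one-sided Wilcoxon)
crc: 10 TFs shared across 3 species (pig-set ratio 0.38)
```

Reading the key lines: the replicate correlation clears the usual > 0.9
bar; the planted conservation fractions (30% functional, 55%
sequence-only) are recovered to within a fraction of a percentage point;
the KS test confirms functionally conserved enhancers sit closer to
genes than sequence-only ones; expression comparisons recover both
planted shifts in the planted direction; and the three-species circuitry
intersection returns exactly the 10 planted shared TFs out of the
26-member first species set (ratio 0.38).

`demo_out/` then contains the full artifact tree — the simulated inputs
(`inputs/`: narrowPeak, bedGraph with library-size headers, GTF, chain,
TSV), per-class element BEDs, the ranked hockey-plot table,
`conservation.tsv`, the state matrix with cluster assignments, DE calls,
CRC membership tables and a `run_manifest.json` recording seed,
parameters, counts and statistics. Identical seeds give byte-identical
trees. A thin CLI wrapper with `simulate` and `demo` subcommands is
installed at `inst/scripts/cre-pipeline.R`.

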