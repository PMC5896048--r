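---
title: "Methods: mutual-rank networks, promoter position bias, and duplication classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutual-rank networks, promoter position bias, and duplication classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrgcn)
```

This vignette documents the statistical procedures in `mrgcn`, the
assumptions behind them, the defaults and why they were chosen, and what the
synthetic-data tests do and do not establish about behaviour on real data.

## Mutual-rank co-expression networks

`mr_network()` log2-transforms abundances with a pseudocount
(`log2(x + 1)`; offset 1 maps zero FPKM to zero and is the common convention
for FPKM-scale data), computes gene-gene Pearson correlations across
conditions, and ranks each gene's correlators by descending r with the gene
itself excluded. The mutual rank of a pair is the geometric mean of the two
directed ranks. MR is used instead of raw correlation because it is robust to
genes with globally inflated correlations (hubs): a pair scores well only if
each ranks highly *from the other's perspective*.

Assumptions: abundances are non-negative, conditions are exchangeable
samples of the transcriptome (no batch structure is modelled), and at least
3 conditions are available. Correlation on the log scale assumes
multiplicative noise, which is standard for FPKM/intensity data.

Numerical choices:

* **Tie-breaks.** Rank ties (equal r) are broken by ascending gene id, and
  so are MR ties in `top_k_cluster()`. Ties are measure-zero for continuous
  data but occur in degenerate fixtures; a deterministic rule makes every
  result reproducible and testable.
* **Zero-variance genes.** Silent (constant) genes cannot be correlated;
  they are excluded from ranking with a warning rather than failing the run,
  because real matrices contain unexpressed genes. Directed ranks are then
  permutations of `1..(G_usable − 1)`.
* **Dense computation.** The full MR matrix is kept in memory. At the scales
  this package targets (≤ a few thousand genes; the reference study uses
  1000 × 60) this is cheap; nothing in the API would change if edges were
  truncated to each gene's top k, because only `top_k_cluster()` output is
  contractually guaranteed.

A guide-gene cluster is the guide's k = 100 lowest-MR neighbours, the guide
itself excluded — the tested set is what is co-expressed *with* the guide
(a flag re-includes it). Two expression platforms (e.g. microarray and
RNA-seq) are handled as two independent network builds; no cross-platform
normalisation is attempted, and `composite_summary()` simply counts, per
category, how many guide networks are enriched on each platform.

## Enrichment

For a cluster of n genes from a universe of N, a category with K universe
members and k cluster members gets the one-sided hypergeometric upper tail
P(X ≥ k) (`fisher_upper()`, computed by `phyper`; the test suite checks it
against direct summation to 1e-12). Benjamini–Hochberg adjustment is applied
**within one cluster** across all categories tested there; per-cluster
families match per-network reporting when many guide networks are
summarised, and the null-calibration test shows the per-cluster familywise
false-positive behaviour is at the nominal rate. Defaults: FDR < 0.05 for
functional categories, FDR < 0.01 for CRE presence (promoter motif content
is noisier, so the stricter threshold).

Category codes are hierarchical dotted strings; a gene annotated `34.19`
counts under `34` as well, and each depth is tested as its own category.
The universe is the set of measured genes (only measured genes can enter a
cluster), not the whole genome. Categories with K < 2 or k = 0 are skipped:
the former margin is untestable, the latter cannot be over-represented.
Cluster genes lacking a promoter are dropped from CRE tests with a warning
(n is reduced accordingly).

## Promoter motif scanning and position bias

Promoters are L = 1000 bases written 5'→3' ending at the TSS. The scanner
tests **every** window position independently (overlapping matches all
count — observed per-motif hit totals in the field imply per-window
counting), expands IUPAC degeneracy exactly, and treats `N` in a sequence as
matching nothing (an unknown base should never create a hit). Positions are
reported as 1-based TSS distances to the motif's TSS-proximal (3'-most)
base, so *small values mean near the TSS*. Reverse-strand mode reports a
reverse-complement match at the forward-strand window it occupies; the
default is forward-only, since strand conventions for published CRE
collections are often unstated and forward-only is the conservative choice.

For a motif with n hits and central position p, `position_z()` computes the
position-bias Z-score. The default **corrected** variant is the exact Z
statistic for the mean of n draws from the discrete uniform on
`1..(L − l + 1)` (mean ≈ L/2, variance `((L − l + 1)² − 1)/12`):

\[ Z = \frac{L/2 - p}{\sqrt{((L - l + 1)^2 - 1)/(12n)}} \]

It is zero when hits centre mid-promoter, positive for TSS-proximal bias,
and standard normal under uniform placement (verified by simulation:
mean within ±0.1 of 0 and KS distance < 0.1 at n = 20–50). A **printed**
variant, `(L/2 + p)/sqrt(((L − l + 1)² − 1)/n)`, is retained behind
`variant = "printed"` for comparability with reports that use that written
form; it is not the default because its sign *increases* with TSS-distal
positions — contradicting the use of the score to find TSS-proximal
elements — and its variance term omits the uniform-distribution divisor 12,
so it is not calibrated. Both variants are computed and reported side by
side in all summaries.

The central statistic p defaults to the **median** of hit distances (robust
to a handful of distal hits in long promoters), with the mean always
reported alongside and available via `central = "mean"`; ranking uses the
selected variant with ties broken by descending hit count then ascending
motif id.

## Duplication classification

Genes are ranked along chromosomes by ascending start (ties by id). All
genes start as singletons; any filtered homology hit makes both ends
dispersed; same-chromosome pairs with rank difference exactly 1 are tandem
and with rank difference strictly below 20 are proximal; anchors of
collinear blocks are WGD/segmental. One class per gene, priority
segmental > tandem > proximal > dispersed.

Collinearity is a simplified anchor-chaining dynamic programme (score =
chain length) per chromosome pair and orientation: chains must be strictly
monotone in rank on both sides (increasing/increasing = parallel,
increasing/decreasing = antiparallel) with inter-anchor gaps ≤ `max_gap` on
both sides; chains are extracted greedily by size, each anchor joining at
most one block, and chains below `min_block_size` are discarded. Defaults
`min_block_size = 5` and `max_gap = 25` mirror common practice for
MCScanX-style analyses; both are arguments, not assertions about any
particular published run. An e-value ceiling (default 1e-5) filters hits
before classification, and hits are symmetrised — direction only matters for
`reciprocal_best_hits()`, which implements plain RBH (lowest e-value, ties
by bitscore then id); conditional e-value learning variants of RBH are out
of scope.

## The synthetic-data generator

`simulation_config()` / `simulate_study()` generate all pipeline inputs with
planted, recorded structure:

* **Expression** — each module has a latent log2 condition profile
  (sd 2 around a baseline of 6, an FPKM-like dynamic range); members equal
  latent + Gaussian noise. When `noise_sd` is not given it is derived from
  the module's `base_correlation` ρ as `latent_sd · sqrt((1 − ρ)/ρ)`, which
  makes the expected within-module Pearson r of log values exactly ρ.
  Values are emitted on the raw scale (`2^z − 1`, truncated at zero) so the
  pipeline's own log transform is exercised.
* **Promoters** — uniform i.i.d. A/C/G/T background (deliberately, so the
  expected background hit count of a motif has the closed binomial form
  `(L − l + 1) · ∏ d_i/4` per promoter, used as a test oracle); planted
  instances overwrite the background at distances drawn uniform or Gaussian,
  never overlapping within a promoter.
* **Genome** — genes laid at fixed spacing; tandem/proximal/segmental events
  placed on free rank slots with a one-rank buffer; every planted pair gets
  a strong hit. Noise hits never join two genes on one chromosome within
  rank difference 20, and never have both ends flanking a planted segmental
  run — otherwise a noise anchor could extend a planted block and the
  planted truth would no longer be the unique correct answer.
* **Annotation** — planted codes on a stated fraction of a module plus a
  background rate; unstructured decoy categories make the BH family
  realistic.

Each stage reseeds from `seed` plus a fixed stage offset, so stages are
individually reproducible and order-insensitive; identical configs produce
byte-identical output files.

`study_config()` fixes the reference study: 1000 genes × 60 conditions, one
40-gene module at ρ = 0.8; category `34.19` on 80 % of the module versus a
2 % background rate; an 8-mer CRE planted Gaussian(mean 250, sd 80) in 60 %
of module promoters and uniformly in 3 % of background promoters; and a
2-chromosome × 200-gene genome with one 10-anchor segmental block, 3 tandem
pairs, 2 proximal pairs, 20 dispersed noise hits, and ≥ 50 hit-free
singletons. The planted CRE is an 8-mer because a degenerate 6-mer occurs by
chance in the majority of random 1 kb promoters, which would make a planted
3 % background presence meaningless; an 8-mer's ~1.5 % background match rate
keeps presence/absence informative. These sizes keep the full test suite and
acceptance script to well under a minute per stage on one CPU while leaving
the planted effects comfortably detectable.

**What passing these tests shows — and does not.** The generator emulates
the *structure* of real inputs (planted co-expression, position bias,
enrichment, duplication geometry) under idealised noise: Gaussian on the log
scale, uniform promoter composition, exchangeable conditions, clean
homology. It does not emulate batch effects, heteroskedastic count noise,
GC/repeat structure in promoters, fragmented assemblies, or paralog-rich hit
tables. Recovery on synthetic data therefore validates the *implementation*
(the statistics do what they claim under their own assumptions), not the
biological sensitivity of the pipeline on any particular genome.

## Degenerate inputs and edge behaviour

* `k` larger than the available neighbours: all are returned, with a warning.
* Constant expression rows: zeroed by `row_zscore()` (warning), excluded
  from ranking by `pearson_matrix()` (warning).
* No hits for a motif: summary row with n = 0 and NA position/Z, ranked last.
* Empty presence tables or clusters with no annotated categories: empty
  enrichment results (an empty *cluster* is an error).
* Readers reject ragged rows, duplicate ids and non-numeric cells with the
  offending line number; off-length FASTA records are excluded with a
  warning.

## Known limitations

* Dense MR computation bounds practical network size to a few thousand
  genes; genome-scale (30k-gene) networks would need blockwise or top-k
  truncated computation behind the same API.
* The collinearity chainer scores chains by anchor count only, not by
  e-value-weighted scoring as full MCScanX does; on noisy hit tables near
  `min_block_size` the block boundaries may differ from MCScanX's.
* No Ka/Ks dating, no position weight matrices, no ontology parsing beyond
  dotted codes, no cross-platform normalisation — all deliberately out of
  scope.
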