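---
title: "Signature conservation scanning: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature conservation scanning: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SigScan)
```

SigScan asks a simple question at compendium scale: once a gene signature
has been extracted from one cohort, do its genes move together anywhere
else? This vignette explains the statistical models behind each stage, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design choices made where the methods left room.

## Signature extraction

**Low-expression filter.** A gene is rejected when its value falls strictly
below the per-sample median — the median over all genes of that sample — in
more than `maxLowFraction` (default 2/3) of samples. The reference medians
are those of the matrix as supplied, before filtering, because the filter is
defined against each sample's full post-normalization profile. This has a
consequence worth stating: removing low genes raises a recomputed median, so
naively re-applying the filter to its own output can reject more genes.
The operation is therefore parameterized by `sampleMedians`; re-applying it
with the original reference is a no-op, and that is the sense in which the
filter is idempotent.

**Stratification and testing.** Samples with driver expression ≥ `highCut`
(default 2) form the high group, ≤ `lowCut` (default 1) the low group; both
comparisons are inclusive and the middle is excluded. Each gene is tested
with the equal-variance two-sample *t* — the classical choice for
moderate-size microarray cohorts, where pooling stabilizes the denominator —
with Welch available via `welch = TRUE`. Genes with zero pooled variance
never yield NaN: equal group means give p = 1; a mean difference over zero
variance is assigned a pseudo-variance floor (the smallest positive per-gene
variance × 10⁻⁶), which keeps the statistic finite and ranks the gene at the
top rather than dropping it.

**Risk level and FDR.** `alpha` is exposed rather than fixed: the analytic
estimate FDR = *m·α/k* makes the interaction visible. With *m* = 14,455
probes and *k* = 57 selected genes, α = 10⁻⁴ gives ≈ 0.025 while α = 10⁻³
gives ≈ 0.25 — the published account of this analysis quotes the 0.1% risk
alongside an FDR of 0.025, which are mutually consistent only at the
smaller α, so the package hard-codes neither.

**Risk scores.** `computeTGS()` and `computeTGSIPI()` apply the published
linear coefficients and class cut-offs. The cut-offs are written as strict
inequalities on both sides, leaving boundary values unassigned; values
exactly at a boundary go to the higher-risk class, the conservative
reading.

## The sign-coordination scan

Each sample is first rank-normalized to (rank−1)/(n−1) with average ranks
for ties. Only orderings survive this transform, which is what makes
cross-platform scanning defensible: any strictly monotone per-sample
distortion leaves every downstream statistic unchanged (a property the test
suite checks end to end).

For an ordered sample pair (i, j) and signature genes covered by the
series, the statistic counts genes with sᵢᵏ − sⱼᵏ > 0. Under the null that
each sign is a fair coin, the p-value is the exact binomial upper tail at
the orientation-maximal count, so a pair is scored by its better direction.
Choices behind that sentence:

- **Ties** (zero difference) are excluded from numerator and denominator by
  default: the sign model is undefined at zero, and rank normalization makes
  ties rare. `tiePolicy = "against"` keeps them in the denominator for a
  conservative variant.
- **Orientation.** Scoring max(k, n−k) with a one-sided tail reproduces a
  scan over ordered pairs. `orientationCorrection = TRUE` doubles the tail
  for an explicit two-orientation correction; it is off by default because
  the selection thresholds were defined on the ordered-pair scale.
- **Numerics.** For n ≤ 64 `binomTail()` sums binomial coefficients over the
  smaller side of the distribution — keeping every summand a small exact
  integer — and divides by 2ⁿ; beyond that the log-space cumulative is used.
  Strict monotonicity in k is asserted only where it is representable:
  near a tail of 1 the step 2⁻ⁿ falls below double epsilon for n ≳ 53.
- **Degenerate pairs.** No informative gene (all ties) gives p = 1, never an
  error mid-scan.

`scanCollection()` keeps each series' best pair, ranks by p-value (ties
broken lexicographically for determinism), and applies the Holm step-down
correction with m = the number of scanned series — one test per series,
since one pair is retained per series; m is configurable because other
accountings are defensible. Selection takes the first `topN` entries of the
ranking that also pass `minProportion`, `maxP` and `maxAdjusted`; the
defaults (250, 0.9, 1.9×10⁻⁸, 3×10⁻⁵) are the published corpus-scale rule
for a 57-gene signature. They scale with signature size: the most extreme
tail a 20-gene signature can produce is 2⁻²⁰ ≈ 10⁻⁶, so cutoffs must be
chosen relative to the coverage at hand. Series covering less than
`minCoverage` (default 0.8, the smallest platform coverage tolerated in the
original corpus) are skipped with a warning.

## Annotation mining and gene-set enrichment

Term mining is deliberately plain bag-of-words: lower-case, strip
non-letters, drop tokens under 3 characters and a built-in stop-word list
(plus expression-study boilerplate such as "dataset" or "microarray"), and
reduce each series to a presence set. Each term occurring in at least
`minOccurrence` series (default 3) is tested with a two-sided Fisher exact
test on the 2×2 table of presence × selection, with a Haldane-corrected
odds ratio when a cell is empty. Multiple testing uses Benjamini–Hochberg
by default (Holm optionally); the original analysis did not state its
correction, so the raw p-values are always reported alongside. No stemming
and no ontology mapping: these would add unstated degrees of freedom.

Gene-set enrichment reproduces the classical GO-report arithmetic: fold
enrichment (c/l)/(T/N) and a one-sided hypergeometric over-representation
tail P(X ≥ c); the under-representation tail is computed into a separate
column rather than folded into a two-sided p, because the reported tables
this reproduces contain only over-represented terms. The background size N
comes from the supplied universe. For the shipped annotation table of the
57-gene signature, N is not printed anywhere; the rows are mutually
consistent with N ≈ 12,982, recovered by inverting the enrichment formula
on the *T cell activation* row (13.076874 × 57 × 209 / 12). The package
derives it that way at run time instead of pretending the value was given.
The table's log₁₀(p) column is treated as a magnitude, −log₁₀(p) ≥ 0; the
source table mixes signs on that column and the inconsistency is not
modelled.

## Neighbor-graph summarization

Co-expression query results are a Boolean matrix m(i, j) over query
(signature) genes × returned neighbors; an edge joins two genes when one is
the neighbor of the other, which also makes a query gene listed by another
query gene a symmetric edge. Neighbors of fewer than `minDegree` (default
3) query genes are discarded as isolated.

Agglomeration starts from singletons and iteratively merges connected
cluster pairs, admitting a merge only if the result remains *fully
connected*: all signature genes pairwise linked and every neighbor linked
to all signature genes of the cluster. The iteration order is unspecified
in prose descriptions of such procedures, and order changes results, so
candidate pairs are scanned lexicographically by smallest member identifier
and merged clusters re-enter the pool — making the output deterministic and
invariant to input permutation (tested). Clusters under `minSize` (default
3) genes are pruned.

Inter-cluster connectivity is the fraction of realizable cross-cluster gene
pairs carrying an edge. The denominator counts only *admissible* pairs —
those with at least one signature gene — because the neighbor relation
cannot produce an edge between two non-signature genes, and counting
impossible pairs would dilute every connectivity toward zero; the naive
all-pairs denominator is available behind `denominator = "all"`. Cluster
pairs at or above `threshold` (default 0.2) become summary-graph edges,
serialized as GraphML.

## What the simulators emulate — and what they do not

`simulateSeriesCollection()` draws i.i.d. Normal(0, `noiseSd`) background
and, in each planted series, adds `pairShift` to the signature genes of one
member of a random sample pair; annotations mix a background vocabulary
with planted terms at elevated rate. Because the scan is rank-based, only
orderings matter, so a Normal background loses no generality against real
intensity distributions. Two things it deliberately does not emulate:
correlated gene–gene background structure (real co-expression makes null
pairs less independent than the fair-coin model assumes) and platform probe
annotation. Consequently, passing recovery tests demonstrates correctness
of the machinery, not the real-data false-positive rate. The one-sided
planted shift also means planted pairs are only *nearly* perfectly
coordinated: the shifted sample's signature genes occupy the top ranks, but
their ranks in the unshifted partner are uniform, so the expected
proportion is just below 1 and approaches it as the signature becomes a
small fraction of the gene pool.

`simulateDriverDataset()` plants a truth-gene block shifted down by
`effect`·sd in driver-high samples, with driver values drawn on either side
of the high/low cuts. Truth genes carry a baseline elevation
(`truthBaseline`, default 1 sd): a gene under-expressed in one stratum can
only survive the low-expression filter if it is expressed above the typical
gene elsewhere, which is exactly the profile of a real signature gene.

`simulateNeighborMatrix()` builds disjoint complete bicliques (each block's
query genes list each other and all block neighbors) and adds spurious
cross-block relations with probability `crossEdgeNoise`. At zero noise
recovery is exact; at 5% noise the deterministic join order keeps recovery
above Jaccard 0.9 because a spurious merge requires a foreign gene to be
linked to *every* signature gene of a cluster.

All generators are deterministic given `seed`.

## Problem sizes and runtime

The test suite exercises the scan on corpora of up to 100 series × 10
samples × 500 genes with a 57-gene signature, the extraction on 5,000-gene
cohorts of 10 vs 10 samples, and agglomeration on planted bicliques of a
few dozen genes with up to 8% noise; the whole suite runs in well under a
minute. These sizes were chosen so that planted effects sit at the
statistical scale of interest (3 sd shifts, p-values between 10⁻¹⁸ and
10⁻⁸) while each test remains a few seconds. The agglomeration is O(n³)-ish
in gene count by construction and is meant for the hundreds-of-genes regime
of filtered neighbor sets, not for whole transcriptomes.

## Known limitations

- The fair-Bernoulli null treats signature genes as independent; real
  co-expression inflates the null tail, so corpus-scale p-value thresholds
  should be read as ranking devices, not calibrated error rates.
- Probe-to-gene mapping is out of scope: identifiers are opaque strings and
  the first occurrence wins on duplicates.
- Annotation mining is monolingual bag-of-words with a fixed stop-word
  list; terms split by hyphenation or inflection are counted separately.
- The enrichment module takes annotation sets as given — no propagation of
  memberships along the GO hierarchy.
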