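---
title: "Rescuing weak but reproducible peaks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescuing weak but reproducible peaks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakrescue)
```

## The problem

A ChIP-seq peak caller reports, for every candidate binding site, a p-value
for enrichment of reads over background, and the analyst keeps peaks more
significant than some threshold. That threshold is a trade-off: a stringent
cut discards weak but genuine binding sites, a permissive cut floods the
result with artifacts. When replicated samples are available there is a
third option: call peaks permissively (e.g. at p ≤ 1e-4), then use
cross-replicate reproducibility to separate weak true sites from noise. A
weak peak that colocalizes with peaks in the other replicates — even weak
ones — carries joint evidence that no single replicate can provide; a peak
private to one replicate, at a permissive threshold, is most likely noise.
`peakrescue` implements this rescue strategy for any number of replicates
and emits a single set of scored consensus regions, plus an
annotation-enrichment z-test to ask whether rescued regions fall in
functional genomic elements.

## The model

### Peak classes

Each peak carries `-log10(p)` of its calling p-value. Given a weak
threshold `w` and a stringent threshold `s` (`s <= w`, both on the p-value
scale):

* **stringent**: p ≤ s — credible on its own;
* **weak**: s < p ≤ w — a candidate for rescue;
* **background**: p > w — removed before any testing; background peaks can
  neither receive support nor provide it.

A p-value exactly at a threshold joins the more significant class. This
matters only for constructed inputs (real calling p-values never sit
exactly on a threshold), but it has to be fixed one way, and "≤" matches
the usual reading of "called at threshold t".

### Fisher combination of colocalized peaks

For an assessed peak, each *other* replicate contributes the set of its
candidate peaks overlapping the assessed one (≥ 1 shared nucleotide,
half-open coordinates; abutting peaks do not overlap). One *test tuple*
consists of the assessed peak plus one overlapping peak from every
contributing replicate; all combinations are considered (the Cartesian
product), so a peak overlapping two peaks in one replicate is tested twice.
Tuples smaller than `c` members yield no test at all: `c` is the minimum
colocalization support demanded, counting the assessed peak itself, and
defaults to the number of replicates.

A tuple of k members with values `-log10 p_i` is scored with Fisher's
combined probability test:

χ² = −2 Σ ln p_i = 2 ln(10) Σ (−log10 p_i),

referred to the right tail of χ²(2k). The tuple passes when the combined
p-value is at most the combined threshold `g`. With k = 1 the test reduces
to the identity, so a single replicate with `c = 1` degenerates to plain
per-peak thresholding at `g`.

### Confirmation, FDR, consensus

* **Biological replicates** tolerate heterogeneity: a peak is confirmed if
  *at least one* of its tuples passes.
* **Technical replicates** demand homogeneity: a peak is discarded if *any*
  tuple fails (and a peak with no tuples is always discarded).

Confirmed peaks of each replicate are then filtered with the
Benjamini–Hochberg step-up procedure at level `alpha`, each peak ranked by
the most significant combined p-value among its passed tests (best
evidence, matching the "any test suffices" confirmation logic). The
BH-selected peaks of all replicates are pooled and partitioned into
connected components under transitive overlap; each component becomes one
consensus region spanning the union of its members and scored by one final
Fisher combination of the members' *original* calling p-values — each
member counts once, so evidence is never combined twice.

### Default thresholds

The defaults `w = 1e-4`, `s = 1e-8`, `g = 1e-6`, `alpha = 0.05`,
`c =` number of replicates correspond to permissive peak calling at 1e-4
followed by a combined threshold two orders of magnitude below the weak
cut. This threshold set was selected, in the study the method derives from,
as the one maximising annotation enrichment over a large transcription
factor panel; the package hard-codes it as the default rather than
providing a threshold-search loop.

## The enrichment z-test

To ask whether a peak set falls preferentially in annotated elements
(promoters, enhancers, CpG islands, ...), the genome of size G is split
into the n₁ nucleotides covered by the (union-merged) peak set and the
n₂ = G − n₁ nucleotides outside it. With k₁ and k₂ the annotated
nucleotides in each part,

p = k₁/n₁, a = k₂/n₂, β = p − a,

and the enrichment score is z = β/σ with the unpooled two-proportion
standard error σ = sqrt(p(1−p)/n₁ + a(1−a)/n₂). β > 0 means a random
annotated position is more likely to lie under a peak than a random
unannotated one. Under the null hypothesis that peak placement is
independent of the annotation at nucleotide resolution, z is approximately
standard normal; the test suite verifies |mean| < 0.1 and SD within
[0.85, 1.15] over 500 null simulations.

Two caveats are worth stating plainly. First, the standard-error formula
treats nucleotides as independent Bernoulli draws. Real annotations and
real peaks are both autocorrelated (they come in runs), so on real data the
effective sample size is smaller than the nucleotide count and z values are
inflated in magnitude; z is therefore best read as a *comparative* score
between peak sets against the same annotation — which is exactly how the
common-versus-specific comparison uses it — rather than as a calibrated
p-value. Second, no multiple-testing correction is applied across
annotation tracks; the panel reports raw z per (subset, annotation) pair.

The common/specific split assigns a consensus region to "common" when it
overlaps any interval of a conservative reference set by at least one
nucleotide, at whole-region granularity: a region partially covered by a
reference peak is still a region the conservative method found.

## Numerical choices

* **All p-value arithmetic is in −log10 space.** Fisher sums, χ² tails
  (`pchisq(..., log.p = TRUE)`), BH comparisons and output columns never
  form a linear p, so combined p-values far below the double underflow
  limit (~1e-308) remain exact. A literal p = 0 in a linear-scale input
  file is a hard error, not a clamp, since clamping would silently change
  Fisher sums.
* **Decisions without tuple materialisation.** All tuples of one assessed
  peak share the same member count k, and χ² is monotone in the summed
  −log10 p of the chosen members. Hence the best tuple takes the
  per-replicate *maximum* overlapping −log10 p and the worst tuple the
  per-replicate *minimum*; "some tuple passes", "all tuples pass" and the
  best combined p used for BH ranking follow from those two extremes. The
  pipeline therefore runs in O(hits log hits) regardless of how many
  tuples the Cartesian product would contain. `enumerate_tests()`
  materialises the tuples explicitly when the individual tests are wanted,
  with a 10,000-tuple safety cap against pathological within-replicate
  peak stacks; the test suite verifies on hundreds of random instances that
  the aggregate path is identical to exhaustive enumeration.
* **Determinism.** Chromosomes are ordered by locale-independent radix
  sort; output rows by (chrom, start, end, replicate, input rank); BH ties
  by input position (the step-up selected set is tie-order invariant, the
  ordering is fixed anyway). Identical input and configuration give
  byte-identical output.
* **Degenerate enrichment inputs.** A peak set covering 0 or all
  nucleotides is an error (a conditional probability would be undefined);
  an annotation covering nothing or everything gives β = 0 and z = 0;
  σ = 0 with β ≠ 0 reports signed infinity.

## What the simulator emulates — and what it does not

`simulation_spec()` / `simulate_peaks()` generate the regimes the method is
designed to separate: reproducible strong sites (−log10 p in 9–12 by
default), reproducible *weak* sites (5–6, i.e. between the default weak and
stringent cuts — rescuable but individually sub-stringent), and
replicate-private noise in the weak range (4–6). Sites are placed
disjointly with a guard gap larger than the coordinate jitter, so peaks
from different sites never merge; noise peaks avoid the sites *and each
other across replicates*, making "replicate-private" literal. That design
makes ground-truth labels unambiguous: a clean run has false-discovery
proportion exactly 0, and any nonzero value indicates a real defect rather
than label fuzz. The annotation track covers each planted site with
configurable probability plus background intervals elsewhere, so
enrichment ordering (specific > common) can be forced by construction.

The simulator deliberately does not model read counts, fragment lengths,
GC bias, or correlated noise between replicates — peak calling is upstream
of this package. Passing tests on simulated data therefore demonstrate the
correctness of the decision logic and the statistics, not robustness to
upstream calling artifacts.

Default sizes (100 sites, 3 replicates, 300 noise peaks per replicate on a
1 Mb genome) keep a full pipeline run in well under a second; the scale
contract (3 replicates × 100,000 peaks in minutes on one CPU) is exercised
with a grid-constructed input in the test suite.

## Open design points, resolved

* **"Colocalized within a certain distance"** is implemented as ≥ 1 bp
  overlap, with no gap-extension knob: the overlap predicate is the one the
  confirmation tests are defined on, and a distance tolerance would add a
  parameter the method's description never quantifies.
* **Tuple formation across ≥ 3 replicates** is the symmetric Cartesian
  product over contributing replicates. "A peak may be tested multiple
  times if it overlaps multiple peaks on another sample" then holds in
  every replicate, not just one distinguished one.
* **Support counting (`c`) is "≥"**, counting the assessed peak: a tuple of
  exactly `c` members is testable.
* **BH is applied to confirmed peaks only** (not all candidates), each
  ranked by its best passed combined p.
* **Within-replicate overlapping peaks** are kept at read time, can end up
  in the same consensus component, but never co-occur in one tuple — tests
  are strictly cross-replicate.
* **σ of the enrichment test** is the textbook unpooled standard error of a
  difference of two independent proportions with nucleotide counts as
  sample sizes; it reproduces the stated N(0, 1) null behaviour in
  simulation. Enrichment is computed genome-wide (one 2×2 tally over all
  chromosomes), not per chromosome.

## Limitations

* The rescue logic is only as good as the permissive calling upstream: a
  weak site the caller never reported cannot be rescued.
* z scores on real annotation tracks are anti-conservative in magnitude
  (see above); compare them between peak sets, do not read them as
  standard-normal quantiles.
* Replicate-private noise is the simulator's model of artifacts; correlated
  artifacts (e.g. shared input biases producing the same false peak in all
  replicates) defeat any reproducibility-based method and are out of scope.
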