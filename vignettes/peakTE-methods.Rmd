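---
title: "Discovering polymorphic TE families from insertion-call VCFs"
author: "peakTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering polymorphic TE families from insertion-call VCFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakTE)
```

## The problem

Transposable elements (TEs) replicate through a genome in bursts, and a
recently active family leaves insertions that are *polymorphic*: present in
some individuals of a population and absent in others. Short-read insertion
callers emit, per sample, a VCF of insertion breakpoints with the inserted
sequence. peakTE turns a directory of such per-sample VCFs into a
population-level picture of TE activity:

1. pool all samples' insertion **sizes** and find enriched size intervals
   ("peaks") — members of one TE family share a characteristic length;
2. cluster the inserted **sequences** within each peak to resolve
   subfamilies that happen to share a size range;
3. annotate cluster representatives against a consensus library;
4. merge insertions across samples into population **loci** with per-group
   allele frequencies and gene-feature context;
5. reconstruct **solo-LTR** and **full-length ERV** insertions, exploiting
   the LTR–internal–LTR anatomy of endogenous retroviruses.

A synthetic-population generator with a complete truth table makes every
stage testable without any external data.

## Peak detection: local density against a rolling-quantile background

TE families occur at wildly different copy numbers, so a global frequency
threshold either drowns rare families or calls noise. peakTE instead works
relative to each size's own neighbourhood.

Let $c_s$ be the number of pooled insertions of size $s$ (1 bp resolution,
default range 100–9000 bp; family sizes are conventionally reported at bp
resolution). The local density is a centred sliding mean,

$$ d_s = \frac{1}{|W_s|} \sum_{t \in W_s} c_t, $$

with $W_s$ a window of width `density_window` (default 50 bp) clipped at
the histogram edges and renormalised by the width actually used, so edge
sizes are not artificially suppressed. The background at $s$ is the
empirical 75th percentile (`background_quantile`) of $d$ over a wider
window (`background_window`, default 500 bp), again centred and clipped —
a pure rolling quantile that includes the focal window (an exclusion
option exists). Maximal runs with $d_s$ strictly above the background
become size clusters; the strict comparison makes a perfectly flat
distribution yield nothing. Runs separated by fewer than `merge_distance`
(default 100 bp) are consolidated transitively, absorbing within-family
length variability; per-run maxima are retained in a `sub_peaks`
diagnostic column because a broad merged region can legitimately contain
several closely spaced maxima.

Two post-merge strength filters are the package's own design choice, made
once: the spec of a rolling quantile alone cannot separate families from
sampling noise, because by construction a noticeable fraction of positions
exceed their own local 75th percentile. A reported cluster must therefore
have (i) peak density at least `min_peak_enrichment` (default 3) times the
background threshold at its peak — at realistic densities the smoothed
noise field sits many standard deviations below three times its own local
quantile, while genuine families run 5–50× their neighbourhood — and (ii)
at least `min_cluster_count` (default 10) members. Both are configurable;
setting them to 0 recovers the bare quantile rule.

The reported `peak_position` is the local maximum of the *raw*
size-frequency distribution within the cluster (ties to the smaller
size). The smoothed density is deliberately not used here: a sharp family
becomes a ~50 bp plateau after smoothing and its argmax can wander
~15 bp off the true mode, whereas the raw mode localises to the bp.

## Sequence clustering within a peak

Within a size cluster the inserted sequences are clustered to resolve
subfamilies. Percent identity between two sequences is the optimal global
alignment score under match = 1, mismatch = 0, gap = 0 — equivalently the
longest-common-subsequence (LCS) length — divided by the longer sequence's
length. The max-length denominator is symmetric and conservative: a
truncated copy cannot score as a full-length match. The LCS is computed by
a bit-parallel row dynamic program in C++ (about 60× the throughput of the
plain DP), cross-checked in the test suite against both a plain-R DP and
an independent alignment library under the same scoring.

Clustering is greedy first-fit: sequences are pre-grouped by length
(± `length_tolerance`, default 10%, relative to each group's founding
member), then each sequence joins the first cluster whose *frozen*
representative (the seeding sequence) it matches at `identity_threshold`
(default 0.85), else it seeds a new cluster. First-fit output depends on
processing order, which the spec of the method leaves open; peakTE uses a
canonical order — descending exact-duplicate multiplicity, then descending
length, then lexicographic — so that the most common variants seed
clusters and results are bit-reproducible. Clusters larger than
`sampling_threshold` (default 200) are subsampled without replacement with
weight $w = 1/(1 + |\mathrm{len} - \mathrm{peak}|)$, overweighting
sequences at the peak size (more likely bona fide family members than
boundary artifacts); the weight's specific form is a package choice, any
strictly decreasing function of the distance would serve. Cluster sizes
are then extrapolated back to the full peak by linear scaling
(round-half-to-even). The reported representative is chosen afterwards by
strategy: modal exact sequence (default), longest, or nearest the median
length, with lexicographic tie-breaks throughout.

## Family annotation

The default annotation route is offline and fully reproducible: each
representative is scored against a user-supplied consensus FASTA by the
same percent identity, and the best hit at `min_identity` (default 0.85)
is reported with its achieved identity; e-value/bit-score fields are `NA`
because this scoring has no extreme-value calibration. An optional client
for a Dfam-style sequence-search API exists behind an injectable fetch
function; it is disabled unless an endpoint is configured, rejects
sequences over 10 kb before any request (the public service imposes length
limits), and degrades to an unannotated record on any failure.

## Population loci, allele frequencies, and structure

Calls within a peak's size range are merged across samples per chromosome
by single-linkage on breakpoint distance. The tolerance default (50 bp)
is the package's judgement call — the method description this implements
never states one, and cross-sample merging is the main free parameter of
the whole procedure; it is exposed prominently and the merged-locus
interval records the spread actually observed. A sample with several
calls at a locus contributes its longest; the locus position is the
rounded median breakpoint.

Allele frequency of a locus in a group is the fraction of that group's
QC-passing samples carrying the insertion — presence/absence, not
genotype dosage, because the input callers do not genotype insertions
reliably. Loci can be filtered on a minimum AF in at least one group
(default 0.75) or in all groups; pairwise shared-locus counts between
groups and an average-linkage Euclidean dendrogram over group AF profiles
summarise population structure. The 2-D sample embedding of the binary
presence/absence matrix uses classical metric multidimensional scaling
(principal-coordinates analysis) on Jaccard distances: deterministic,
standard in population genetics, with axis signs fixed for
bit-reproducibility. Nonlinear neighbour-embedding methods can render the
same structure; PCoA was chosen as the package's embedding because it is
exactly reproducible and dependency-light, and the tested contract — a
finite, deterministic 2-D layout in which groups with disjoint high-AF
locus sets separate — does not require nonlinearity.

Gene-feature context comes from a user GTF: the feature at each locus
breakpoint is reported with precedence CDS > UTR > exon > intron >
intergenic, so the categories are disjoint, with the gene id attached
inside gene bodies.

## Solo-LTR and full-length ERV reconstruction

An ERV integrates as LTR–internal–LTR; recombination between the two
identical LTRs usually excises the internal region, leaving a solo LTR.
An active LTR family therefore shows a sharp peak at the LTR length, while
full-length elements hide among similarly sized LINE insertions. The
reconstruction route:

1. build an LTR consensus from all insertions in the LTR size window
   (default 1370–1380 bp) — modal length, then per-column majority vote
   (ties alphabetical);
2. keep loci with a carrier at ≥ 85% identity to that consensus;
3. merge loci within `merge_distance` (default 10,000 bp, a deliberate
   overestimate of the internal length so paired LTRs whose partner call
   was missed still merge);
4. intersect merged loci (padded by 50 bp) with all calls strictly longer
   than `internal_min` (default 4,000 bp, a conservative underestimate of
   the internal region);
5. split each candidate at `floor(len/2)` and scan every window of the
   consensus length (stride 10 bp, plus the terminal windows, evaluated
   first because LTRs sit at the element's ends) in each half; the
   candidate is full-length iff both half maxima reach the identity
   threshold. By default each half's scan region extends one consensus
   length across the midpoint, so an LTR straddling the split cannot be
   missed by both halves. Identical candidate sequences are validated
   once. Truncated stored sequences are rejected with a distinct flag.

A single narrow LTR window misses shorter LTR variants; several windows
may be supplied per run and their loci are pooled before merging.

`brute_force_internal_scan()` is the validation oracle: every call above
the length floor is scored directly against an internal-region consensus.
Here identity is normalised by the *consensus* length (coverage), not the
longer sequence: a full-length call contains the internal region plus two
LTRs, so under max-length normalisation an exact embedded internal region
would score only ~0.62 and the oracle could never confirm the peak
route's calls. Under coverage normalisation an exact embedded internal
scores 1.0 and the peak route's positives are provably a subset of the
scan's.

## The synthetic generator: what it emulates, and what it does not

`simulate_population()` emulates the statistical structure the pipeline
assumes: families with characteristic modal lengths and Gaussian length
jitter, per-copy point-substitution divergence from a family consensus,
length adjustment by 3' truncation/random padding (mimicking the terminal
truncation common in real elements while keeping consensus identity
high), group-stratified Bernoulli carrier status per locus, ERV loci
emitting full-length elements in some carriers and solo LTRs in others
(every full locus carries at least one of each form, so it is
discoverable from its LTR-sized calls), and a uniform-length,
random-sequence insertion background. Loci are placed with a minimum
spacing (default 200 bp, 2× the breakpoint tolerance) so locus-merging
tests are unambiguous; collisions can be forced by shrinking the spacing.
Everything derives deterministically from one seed, and a truth table
maps every emitted record to its origin.

The generator does *not* emulate read-level artifacts: breakpoint errors
beyond a uniform ±20 bp jitter, caller false negatives correlated with
repeat context, chimeric or partially assembled inserted sequences,
genotype dosage, or reference bias. Passing tests therefore demonstrate
the correctness of the algorithms under the model's assumptions, not
caller-level robustness on real cohorts.

## Numerical and degenerate-input conventions

* Windows are centred, edge-clipped, and renormalised by actual width.
* Rolling quantiles use R's default (type 7) definition.
* Comparisons at thresholds: density must *strictly* exceed the
  background; identity thresholds are inclusive (≥); internal-candidate
  length is strictly greater than the floor.
* Ties resolve deterministically everywhere: smaller size, smaller
  position, lexicographically smaller sequence or name.
* VCF positions are 1-based; all internal interval arithmetic is 0-based
  half-open; BED exports are 0-based half-open.
* Insertion length precedence: SVLEN-type field, else inserted-sequence
  length, else the record is skipped with a warning.
* Stored sequences are capped at 10 kb (`truncated` flag); truncated
  sequences are excluded from identity computations and annotation.
* The per-sample QC count (default: reject below 1000 calls) is applied
  after the size filter by default, configurable to before.
* Empty inputs yield empty outputs; an empty sample fails QC when a
  minimum is set.

## Problem sizes used by the test and acceptance suites

The bundled suites run synthetic populations sized for interactive use:
peak-detection properties use 2,000-call uniform backgrounds with
200–500-copy planted families over 20 replicates; clustering oracles use
100 randomized instances of up to 50 sequences; locus/AF recovery uses
three groups of 20 samples; ERV reconstruction plants 20 full-length
elements, 200 solo LTRs and ~300 LINE-like decoys in a 20-sample cohort.
These sizes were chosen so the full suite completes in about a minute
while keeping every binomial check at usable power.

## Known limitations

* Greedy first-fit clustering is order-dependent by construction; the
  canonical order stabilises it but is still a heuristic, and
  representatives are frozen at seeding during the pass.
* Percent identity by LCS scoring has no mismatch penalty; two unrelated
  random nucleotide sequences of equal length score ~0.65, so thresholds
  below ~0.7 are not meaningful for this metric.
* A full-length ERV locus with no solo-LTR calls in the population is
  invisible to the peak-based route (only the brute-force scan can find
  it) — the same failure mode the method's validation describes.
* Peaks are reported without significance estimates; the strength filters
  are calibrated heuristics, not tests.
* AF is defined per sample, not per chromosome; fixed heterozygous and
  homozygous loci are indistinguishable.
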