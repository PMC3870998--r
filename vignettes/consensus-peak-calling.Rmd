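---
title: "Consensus peak calling with MetaPeaks: model, parameters and design"
author: "MetaPeaks authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus peak calling with MetaPeaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaPeaks)
```

# Why a consensus engine

ChIP-seq peak finders embody different statistical models — sliding-window
enrichment, hidden Markov models, strand-cross-correlation — and therefore
return different peak sets, with different boundaries and scores on
incomparable scales, for the same library. No single tool is uniformly
best. MetaPeaks treats the peak lists themselves as the data: each caller
becomes a voter, and regions supported by several voters (or scoring
highly after normalization) become consensus peaks. The package starts
where the callers stop; it does not run them, and BAM/SAM-to-peak
conversion is out of scope by design.

All internal coordinates are 0-based half-open (the BED convention),
surfaced through `GRanges` in the usual 1-based closed form. The published
voting example (intervals [0,7), [9,15), [5,25), [10,20); thresholds 2 and
3) reproduces exactly under this reading, which is why it was chosen.

# Score normalization

Let $s$ be one caller's raw scores, $N$ its own peak count, and $M$ the
largest peak count any caller in the run returned (`maxNoOfPeaks`,
computed once per run across callers). The five methods:

* **Normal** — $\lceil((s-\bar s)/\mathrm{sd} + k)\,M\rceil$ with target
  mean $k$ = `normalShift` (default 3) and *sample* standard deviation
  (the $n-1$ denominator; the reference example — scores 2, 4, 4, 8, 12
  with sd printed as 4 — only holds with $n-1$). Scores that land negative
  sit more than $k$ standard deviations below the mean; they are set to 0
  but the peaks are kept, so voting still sees them. Under a perfectly
  gaussian score distribution the truncated fraction is
  $\Phi(-3) \approx 0.13\%$; real score distributions are heavier-tailed
  upward, so usually nothing truncates. BED mode only.
* **Naive quantile** — $\lceil (s/q_n)\,M\rceil$, where $q_n$ is the
  element at 1-based index $\lceil q\,n\rceil$ of the caller's ascending
  scores. This specific empirical-quantile definition is the only common
  one consistent with the reference example ($q=0.8$ on five scores
  selecting 8). Default $q = 0.75$.
* **Average** — as naive quantile with the mean as divisor, rounded to the
  *nearest* integer. The reference example maps 3.33 → 3 and 13.33 → 13,
  which rules out the ceiling used everywhere else; we follow each printed
  example literally, so average is the one method with round-half-up.
* **Rank** — peaks sharing a score form a cluster; ascending cluster $i$
  (sizes $n_i$) gets $\lceil (n_i/2 + \sum_{k<i} n_k)\,M/N \rceil$. A
  caller's top cluster approaches $M$ regardless of its score scale.
* **Top rank** — clusters ranked *descending* from $M$:
  $\lceil M - (n_i-1)/2 - \sum_{k<i} n_k \rceil$. Callers returning fewer
  peaks (assumed more conservative, hence fewer false positives) get
  systematically higher scores than under rank. The subtracted cumulative
  term is fixed by the worked example (raw scores 10, 9, 7.5, 7.5, 6 for
  input 12, 8, 4, 4, 2 with $M=10$).

All five are monotone in the raw score and touch nothing but scores.
Degenerate inputs: zero sample sd (all scores equal) maps everything to
$\lceil kM \rceil$ with a warning rather than failing; a zero quantile or
zero mean is an error since division is undefined. Ceiling operations
subtract $10^{-9}$ first so that values which are integers up to floating
error do not get bumped a full unit.

# Aggregation and selection

`segmentPeaks()` overlays all callers (overlapping peaks *within* one
caller were already merged at load time, keeping the maximum score, so a
caller casts at most one vote per base) and partitions the covered genome
at every peak boundary via `GenomicRanges::disjoin`. Each maximal
constant-coverage segment carries its distinct-caller vote count and the
sum of normalized scores of covering peaks.

Selection operates at segment granularity:

* **voting** keeps segments with votes ≥ `minRank`;
* **minFP** computes MaxP, the highest aggregated score among segments
  with votes < `minRank`, and keeps segments scoring strictly above it
  (ties at MaxP are excluded — the strict inequality as stated);
* **minFN** computes MinP, the lowest aggregated score among qualifying
  segments, and keeps segments scoring ≥ MinP. The inclusive comparison is
  a deliberate reading: a strict one would exclude the very segment that
  defines MinP, contradicting the rule's purpose of never losing a
  well-supported region. Consequently minFN output always covers every
  qualifying segment, and minFP output never exceeds them.

Exactly contiguous kept segments merge into one reported region (1-bp gaps
are *not* bridged — a gap means some caller boundary separated the
regions); a merged region is annotated with the maximum votes and maximum
segment score among its members, since no post-merge score is otherwise
defined.

`runConsensus()` analyzes one chromosome at a time and concatenates, as a
per-chromosome tool chain would. For voting this equals a whole-genome
pass (votes are local). For minFP/minFN the MaxP/MinP thresholds — and the
normalization operands — are therefore *per chromosome*; a global
threshold would contradict the one-chromosome-at-a-time design and make
results depend on which chromosomes happen to be co-loaded.

# WIG mode

WIG tracks keep peak shape: fixed-width steps with one score each. The
pipeline unifies all tracks to the smallest span present, normalizes step
scores per track (only average and naive quantile — ranking signal steps
or assuming gaussian step scores is statistically unsound, so those
methods are rejected in WIG mode), sums overlapping steps positionwise and
optionally applies an inclusive score cut-off.

Numerical choices in `unifySteps()`: steps whose span is a multiple of the
target and whose starts lie on the target grid split exactly. Anything
else (misaligned starts, non-divisible spans — e.g. spans 3 and 2) cannot
be represented exactly at the target span at all; such tracks are
resampled per base onto the absolute grid anchored at coordinate 0, a
window's score being the mean over its bases with uncovered bases counting
0, and only windows containing a covered base emitted. This conserves
total score mass ($\sum \text{score}\times\text{span}$) exactly in every
case, and is the identity in the divisible case, which is the only one a
step-based format normally produces. Step scores standing in for peak
scores, and the maximum step count standing in for $M$, is the natural
transliteration of the BED formulas; it is isolated in
`normalizeWigTrack()` should a different convention be preferred.

# Evaluation

Against a truth set of intervals curated as true positive, false positive
or ambiguous, `intersectWithTruth()` counts TP at truth-interval level (a
fragmented call over one site earns one TP, not several) and FP at
called-region level (a region overlapping no TP interval), with one-base
overlap sufficing; regions whose only annotated overlap is ambiguous are
excluded from both counts. `performancePoint()` maps the counts to
$y = \mathrm{TP}/|\text{truth TP}|$ (sensitivity) and
$x = \mathrm{FP}/(\mathrm{TP}+\mathrm{FP})$ (false-discovery proportion; 0
when nothing is called), and scores a configuration by its Euclidean
distance to the perfect corner $(0,1)$. The axis definitions are a design
choice — the distance-to-$(0,1)$ construction requires axes on $[0,1]$
with a perfect corner, and precision-style $x$ is the standard choice for
peak benchmarking; the choice is confined to `performancePoint()`.

Across datasets, `combinedRanking()` sums within-dataset ranks of the
distances (average ranks on ties — ties are unaddressed in rank-based
scores otherwise), removing the dominance of the hardest dataset, and
`averageNormalizedDistance()` studentizes distances within each dataset
before averaging. Lower is better for all three measures; they provably
agree whenever one configuration dominates every dataset.

# The simulator: what it emulates, and what a green test means

`simulateStudy()` is the package's stated world for end-to-end checks:

| parameter | default | rationale |
|---|---|---|
| genome length | 1 Mb | one-chromosome working unit; keeps per-base oracles feasible |
| sites | 200 | typical order for a specific TF on a 1 Mb window benchmark |
| site width | 150–400 bp | TF ChIP-seq fragment-level peak widths |
| sensitivity | 0.9 | good callers recover most true sites |
| false peaks | 0.3 × sites | noticeable but minority contamination per caller |
| score scales | 1, 10, 100 | the score-range disparity that motivates normalization |
| score shapes | gamma, shape 4 (true) vs 2 (false) | right-skewed scores; true sites stochastically higher |
| jitter | 25 bp | boundary disagreement between callers |

False peaks are placed away from all annotated intervals so evaluation
labels stay unambiguous, and each caller's false peaks are independent —
which is precisely why voting works: caller-specific noise rarely
replicates across callers. Everything is deterministic given seeds
(byte-identical BED output).

What the simulator does *not* model: read-level noise, fragment-length
effects, copy-number or mappability artifacts (which produce *correlated*
false peaks across callers), broad histone-mark domains, and caller score
distributions with heavy inter-caller correlation. A green simulation test
therefore establishes that the engine's mechanics behave as designed under
the stated world — not that any particular consensus configuration is
optimal on real data.

# Known limitations

* minFP/minFN compare scores at segment granularity; comparing at merged-
  region granularity is a defensible alternative and would need only a
  different selection step.
* Strand is ignored throughout; peaks are strandless intervals.
* WIG declaration blocks on one chromosome with one span are coalesced on
  reading (the underlying parser does not preserve block boundaries);
  writing re-splits at gaps, so round-trips are exact at track level.
* bigWig/bigBed and BAM/SAM inputs are out of scope; supply BED/WIG.
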