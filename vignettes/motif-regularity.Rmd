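---
title: "Measuring temporal regularity of shared motifs in long singing performances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring temporal regularity of shared motifs in long singing performances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifcv)
```

## The model and its assumptions

A *performance* is an ordered sequence of phrases, each labelled with a
phrase type and annotated with the motifs it contains. All statistics in
this package are functions of that discrete sequence only: time is
measured in phrases, never in seconds, which makes every measure
invariant to recording length and tempo.

For a unit type $u$ (phrase type or motif) occurring at positions
$p_1 < p_2 < \dots < p_k$, the inter-phrase intervals are the positional
differences $d_i = p_{i+1} - p_i$. The positional convention (a strict
4-cycle gives intervals of 4, not 3) is pinned by the periodic
worked example; an `interval_mode = "exclusive"` option provides the
"phrases strictly in between" reading for comparison. A motif occurring
several times inside one phrase counts once for that phrase: intervals
are in whole phrases.

Each unit's intervals are normalized by their own mean
($\mathrm{IPI}_u / \overline{\mathrm{IPI}_u}$), so that frequent and
rare units contribute on the same scale; the normalized values of all
units are pooled and summarized by

$$\mathrm{CV}^* = \frac{\sigma(\mathrm{IPI}^*)}{\mu(\mathrm{IPI}^*)},$$

the coefficient of variation of the pooled stream. Because every
normalized subset has mean exactly 1, the pooled mean is 1 and
$\mathrm{CV}^*$ equals the pooled standard deviation. We use the
*population* s.d. (divisor $N$): it reproduces the idealized alternating
$\{1,3\}$ stream's value of exactly $0.5$, which the sample s.d. does
not; `sd_type = "sample"` is available. Unit types with a single
interval contribute one normalized value of 1.0 (they are part of the
pooled set but carry no dispersion information); a flag excludes them.

Two levels are computed: $\mathrm{CV}^*_{ph}$ over phrase types and
$\mathrm{CV}^*_m$ over motifs. When every phrase type carries exactly
one exclusive motif the two pooled streams coincide and the scores are
equal; note that mere absence of sharing is not sufficient — a type
carrying two exclusive motifs duplicates its interval stream in the
motif-level pool and the pooled dispersion can differ.

## Reference models

* **Shuffled null** (`shuffled_null`): phrase order is permuted
  uniformly (each phrase gets a pseudo-random key and the sequence is
  sorted by key); whole phrase records move together. The mean CV* over
  replicates (default 100; the source procedure does not state a count)
  is chance level for a bird with that phrase-type histogram.
* **Bigram Markov model** (`estimate_bigram`, `cv_synth`): first-order
  transition probabilities are estimated from the singing order; the
  final phrase contributes no outgoing transition. Synthetic sequences
  of the original length are simulated — the first phrase drawn from
  the empirical phrase-token frequencies (a "phrase at random" is read
  as a token, not a type), dead-end states restarting from that same
  distribution so the length is always exact — and the mean motif-level
  CV* over 100 replicates is the model's score.
* **Permuted Markov models** (`permute_labels`, `rank_bird`): the same
  transition structure with phrase-type labels permuted,
  $T'[i,j] = T[p(i), p(j)]$. Phrase-level interval statistics are
  distributionally invariant under this action (tested); motif-level
  statistics change because the motif map stays attached to the labels.

The *rank* procedure draws 100 distinct non-identity permutations
uniformly (the source does not state with/without replacement or
whether identity was excluded; we exclude it, reading the bird as
standing outside its 100 alternatives), scores each with `cv_synth`,
and ranks the bird's own score among them: rank = 1 + number of
permuted means strictly below, ties counted as below (the conservative
permutation-test convention), capped at the number of permutations so
that probability = rank/100 stays in (0, 1] — the printed pairing of
rank 4 with p = 0.04 pins probability = rank/n, not rank/(n+1).
Complexity is the number of non-zero transition-matrix entries (a
Kolmogorov-complexity proxy: the length of the shortest "programme"
that regenerates the syntax).

A synthetic replicate can, rarely, contain no repeated unit at all
(e.g. a permuted chain that is nearly absorbing in a motif-free state);
its CV* is undefined and the replicate is dropped from the model mean.
Real singing data do not produce this case.

## The synthetic world

The generator (`generator_config`, `simulate_bird`) states one world
and the tests live in it:

* `n_types` phrase types (field repertoires span roughly 3–43, average
  around 21; tests use 5–8 so that 100 distinct label permutations
  exist and matrices are estimable from one performance);
* `performance_length` 300 by default (recordings average ~32 min,
  roughly 380 phrases at ~5 s per phrase-plus-pause; 500 where a single
  realization must carry a directional comparison);
* `sharing_degree` 2: each motif is carried by $1 + \mathrm{Pois}(1)$
  types; with `sharing_degree = 1` motifs are assigned round-robin so
  nothing is shared;
* `density`: fraction of admissible transitions. The support is seeded
  with a random Hamiltonian cycle (guaranteeing a single recurrent
  class) before extra edges are added; row probabilities are symmetric
  Dirichlet with shape `concentration` (default 1; values < 1 give
  dominant, stereotyped transitions such as 80/20 splits);
* `optimization`: the label-to-transition assignment is chosen among
  `n_candidates = 100` random permutations (matching the scale of the
  100-permutation rank procedure) as the minimizer ("optimized"),
  maximizer ("anti-optimized") or a uniform draw ("random") of the mean
  synthetic motif-level CV*. Candidates are scored with 20 Monte-Carlo
  replicates of length 200: with only a handful of replicates the
  argmin over 100 candidates is noise-dominated and "optimized" birds
  were observed to be barely optimized at all.
* onset jitter s.d. 5 ms (no quantitative field value exists; 5 ms is
  small relative to the 150–450 ms inter-syllable gaps yet large enough
  to exercise the front end);
* audio: constant-frequency tone bursts per syllable (0.5–3 kHz band,
  5 ms cosine ramps, 80 ms duration), phrases separated by 2–3 s
  pauses, optional white noise at a chosen SNR. Timbre, pitch contours
  and Wiener entropy are deliberately not modelled: the front end uses
  onsets only.

What a green synthetic test does **not** establish: that field
recordings behave this way. The generator has no within-type acoustic
variability beyond onset jitter, no drift or higher-order syntax, no
background transients, and its motif annotation is exact. The worked
examples and closed-form limits are the only absolute anchors.

## Acoustic front end: numerical choices

Segmentation thresholds the 1 kHz mean-absolute-amplitude envelope at
median + 3 MAD (falling back to 2% of the maximum when the MAD
degenerates on clean audio) and merges active runs separated by less
than `min_pause = 1.5` s — phrases are separated by 2–3 s pauses, so
1.5 s splits cleanly.

Onset detection normalizes amplitude (detection is scale-invariant up
to floating-point rounding), rectifies and smooths the signal with a
`smooth_ms = 10` moving average *at the native sampling rate* before
sampling the envelope at 1 kHz — averaging 1 ms frames directly cannot
smooth a 500–600 Hz carrier and leaves ripple in the derivative — then
marks local maxima of the envelope first-difference above
median + `threshold_k = 5` MAD. The MAD is floored at 5% of the peak
derivative: on clean synthetic audio more than half the derivative is
exactly zero (MAD = 0), and at moderate SNR the MAD tracks the noise
floor; the floor keeps the published rule usable in both regimes.
Maxima closer than the smoothing window are merged (largest wins). The
point process is binarized at 1000 Hz with the first onset defining
phrase time zero; two onsets rounding to the same 1 ms sample raise an
error rather than silently merging.

## Clustering: design in the open

The reference workflow delegated phrase sorting to an external
spike-sorting toolbox with unspecified internals. This package defines
the method explicitly: trains are compared by the cosine similarity of
their Gaussian-smoothed forms (s.d. `sigma = 0.01` s, first-onset
aligned), computed in closed form —
$K(a,b) = \sum_{ij} \exp(-(a_i - b_j)^2 / 4\sigma^2)$, normalized —
which is exactly the infinite-support version of discretizing,
zero-padding to the longest phrase and correlating. The similarity
graph drops edges below an adaptive threshold and is partitioned by
modularity-maximizing multilevel (Louvain) community detection.

The threshold default deserves a note: an earlier design used the
median off-diagonal similarity, but with $K$ planted types most pairs
are between-type and every pair shares the aligned first onset, so the
median sits *inside* the between-type similarity mode; enough
moderate-weight between-type edges survive that modularity merges
well-separated clusters (~40% failure on planted partitions). The
default is therefore an Otsu (valley) threshold on the off-diagonal
similarities, which separates the within-type and between-type modes;
recovery of well-separated planted templates is then essentially exact.
The semi-automatic manual refinement of near-identical variants is
replaced by an optional second within-cluster pass (`refine = TRUE`).

## Cohort statistics

Paired t-tests compare per-bird observed and model scores (differences
model − observed, df = n − 1); identical vectors return t = 0, p = 1,
while constant non-zero differences are refused as degenerate. The sign
test for ranks below the 50th percentile is one-sided binomial
(the directional claim), with exact-median ranks dropped. Pearson
correlations use the standard t-distributed two-sided p. The "effort"
score correlated with complexity is `n_perm + 1 − rank`, so that the
expected positive association reads directly. No multiple-testing
correction is applied (none is applied in the source workflow).

## Known limitations

* The rank procedure requires at least 5 observed phrase types (for
  100 distinct non-identity permutations) and at least one shared
  motif; performances violating this are refused, and the synthetic
  acceptance cohorts redraw such birds.
* First-order models capture only bigram structure; higher-order
  regularity in the data inflates observed regularity relative to the
  synthetic baseline by design.
* The front end assumes phrases are louder than the noise floor and
  syllables at least ~20 ms apart; it does not implement spectral
  noise subtraction.
* `assign_labels` optimizes over a random sample of labelings, not the
  full orbit; with dense, weakly structured matrices even the true
  optimum may offer little motif regularity, so "optimized" birds are
  meaningful only in worlds whose syntax has structure to exploit
  (sparse or concentrated transition matrices).
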