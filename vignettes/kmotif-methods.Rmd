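---
title: "Quantifying open-field behaviour with symbolic motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying open-field behaviour with symbolic motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmotif)
```

## The model

`kmotif` treats an open-field recording as a document written in an
alphabet of discretized spatial states, and a behaviour as a recurring
phrase in that document. The pipeline has five stages, each exposed as
package functions and composed by `kmotif()`:

**Trajectories.** A session is a regularly sampled series of `(x, y)`
positions in cm (default frame interval 0.040 s). Tracking dropouts are
linearly interpolated when they span at most `max_gap` frames (default 25
frames = 1 s at the default frame rate); longer gaps reject the recording
(`clean_trajectory()`), because interpolating across seconds of missing
data would fabricate movement. Leading or trailing invalid runs cannot be
interpolated; short ones are trimmed instead. Sessions are cut into
fixed-duration segments (default 10 min, `segment_trajectory()`), which
multiplies the number of data points per subject; the trailing remainder is
dropped rather than padded, since padding is a windowing concern that SAX
already handles internally.

**Spatial relations.** Motifs in raw coordinates cannot express
"circling an object" independently of where the object stands, so each
segment is reparameterised into four series (`spatial_relations()`):
absolute position (2-D), per-frame displacement (2-D, prepended with
`(0, 0)` so every relation has the segment's length and SAX windows stay
aligned), distance to the nearest object centre (1-D), and distance to the
nearest boundary point, `min(x, y, side - x, side - y)` (1-D). Object
distance is measured to the centre: no object geometry beyond the centre
point is modelled. The boundary is the full virtual square (default
200 cm), consistent with the zone grid it replaces.

**SAX.** Each series is averaged over windows of `w` frames (`paa()`;
the tail is padded with the last value so the output length is
`ceiling(n/w)`) and each mean mapped to one of `alpha` bins
(`discretize()`). Bins (`fit_bins()`) are equiprobable under a normal
distribution with the mean and standard deviation of the data pooled over
*all* subjects — one shared alphabet, so the same symbol means the same
thing in every recording. Bins are half-open `[lower, upper)` with the
extreme bins open to infinity: the phrase "the highest bin whose lowest
value is lower than the given value" and a closed-interval bin listing
cannot both hold at the boundaries, so the half-open convention was adopted
and is asserted in the tests (a value equal to a breakpoint belongs to the
bin above). An `equal_width` mode reproduces the classical linear zone
grid (5 bins per dimension = 25 zones) used by T-pattern-style analyses;
`visit_entropy()` (base-2 Shannon entropy of symbol frequencies; an
arbitrary but fixed base, since only comparisons matter) quantifies how
uniformly either binning spreads visits. Two-dimensional relations are
discretized per dimension and recombined into `"i:j"` pair symbols
(`pair_dimensions()`), giving an effective alphabet of `alpha^2`.

**Sequitur.** `induce_grammar()` builds a hierarchical grammar from the
symbol series while maintaining digram uniqueness and rule utility; the
rule set both compresses the series and names its recurring subsequences.
The implementation is the classic pointer-based, digram-indexed algorithm
(in C++); two subtleties matter for correctness and are covered by
property tests over thousands of random sequences. First, overlapping
occurrences of a digram inside a run of equal symbols (`b b b`) are left
alone, and when relinking removes the indexed occurrence of such a run the
overlapping neighbour is re-indexed — without this, digram uniqueness is
silently violated. Second, occurrence counts follow the recurrence
`c(S) = 1`, `c(s) = sum over rules t of (occurrences of s in the body of
t) x c(t)`; the per-occurrence multiplicity is required (a rule used twice
inside one body contributes twice). Counts are verified against a
brute-force derivation-tree rewrite. They are *derivation* counts: an
occurrence of a rule's expansion that spans a boundary between two other
rules is not attributed to the rule, so `c(s)` is a lower bound on the
number of non-overlapping occurrences of the expansion in the series —
the tests assert exactly this bound rather than equality.

**Motifs, interestingness, features.** Candidates are the terminal
expansions of all non-start rules (`collect_candidates()`); the start rule
is excluded since its expansion is the whole input. Arbitrary substrings
are deliberately not enumerated — the grammar's rules *are* the motif
inventory, which keeps the candidate set linear in the input. Frequencies
are aggregated across the segments of one class, per relation. Candidates
are ranked (`interestingness()`) by one of
`I1 = f*L*d`, `I2 = f*log(L)*log(d)`, `I3 = L*log(f)*log(d)`,
`I4 = d*log(f)*log(L)`; logarithms are natural — any fixed base rescales
all scores by a constant and preserves the selection. For occurrence
counts measured in the data, frequency is anti-monotone in motif extension
(every occurrence of `m + s` contains one of `m`), so frequency and
length/diversity pull in opposite directions and the four measures trade
them off differently. Ties are broken by descending length, then
lexicographically, making selection deterministic across platforms. The
`k` best per class and relation (`select_top_k()`) form the motif set; a
segment's feature vector is the vector of `k*n*r` greedy non-overlapping
occurrence counts (`count_motif()`; overlapping counting is available but
off by default, matching how grammar-derived occurrences arise).

## Evaluation and tuning

`cross_validate()` runs stratified k-fold cross-validation (default 10
folds; per class, shuffled indices are dealt round-robin, so fold class
counts deviate from proportionality by less than one) with four pluggable
classifiers behind a fit/predict contract: Gaussian naive Bayes
(`e1071::naiveBayes`), decision tree (`rpart`), multilayer perceptron
(`nnet`, one hidden layer of 100 units, decay `1e-4`, 200 iterations) and
k-nearest neighbours (`class::knn`, 5 neighbours) — widely used defaults,
deliberately untouched. Scoring is the class-size-weighted F1
(`weighted_f1()`): per-class F1 weighted by class proportion `|c|/N`. A
variant that instead divides each class's F1 term by the raw class size is
provided as `"literal_eq10"` for auditability; it shrinks with class size
and is not a sensible default, so the standard weighting is used
everywhere.

`kmotif_cv()` cross-validates the whole pipeline. By default motif
selection is redone inside every training split so held-out segments never
influence which motifs become features. SAX bins, however, are fitted once
on all segments passed in: a shared alphabet across subjects is part of
the method's design, and this mild dependence is accepted and documented
rather than hidden. Symbol series and grammars depend only on `(w, alpha)`
and are cached across folds, which makes re-selection cheap.

`tune_kmotif()` implements the search protocol: a per-subject 90/10
development/holdout split (`split_holdout()`), steepest-ascent
hill-climbing (`hill_climb()`) on the integer grid over `w ∈ [5, 50]`,
`alpha ∈ [2, 15]`, `k ∈ [1, 10]` with exhaustive search over the four
measures, objective = mean cross-validated weighted F1 on the development
set. The neighbourhood (±1 in one coordinate), the number of random
restarts (5, seeded) and the step size are choices made here for
determinism and coverage — a climb accepts only strict improvements, so it
cannot cycle, and the full trace is recorded. The holdout is scored
exactly once, with parameters frozen.

`baseline_features()` provides the two reference representations used for
comparison: the flattened coordinate sequence (truncated to the cohort
minimum length, since nothing in the protocol specifies how unequal
lengths should be reconciled) and the four-number
mean/variance-per-dimension summary (population variances).

## The synthetic cohort generator

Real quinpirole open-field recordings are consortium-held and not public,
so `generate_cohort()` produces cohorts with the statistical structure the
method assumes, and the package's end-to-end claims are made on these. A
session is a chain of behavioural bouts:

- *explore* — a correlated random walk: speed `N(15, 5)` cm/s truncated at
  0, heading driven by AR(1) turning increments (coefficient 0.97, sd 0.25
  rad), folded into the arena by reflection; bout length exponential with
  mean 20 s;
- *object visit* — 30 % of non-loop bouts: straight travel at 20 cm/s to a
  random object, then orbiting it at radius 8 cm for an exponential mean
  5 s dwell;
- *loop* — with probability `repetition_strength` per bout for case
  subjects only: a fixed stereotyped circuit between the first two arena
  objects (orbit at 12 cm, crossings at 25 cm/s), followed cyclically for
  an exponential mean 15 s, with Gaussian positional jitter of sd
  `noise_sd` (default 2 cm).

Speeds (≈5–30 cm/s), bout durations and the four-object 200 cm arena are
in the range typical of rat open-field work. At
`repetition_strength = 0` case and control subjects run the identical
generative process (the loop branch consumes its random draw either way),
so the classes are exchangeable by construction; the tests verify this
with a two-sample KS test on step lengths thinned to one sample per 10 s —
thinning matters, because consecutive steps are strongly autocorrelated
and a naive test on every frame would reject for reasons that have nothing
to do with class differences. At the default strength 0.8 the pipeline
with `w = 15`, `alpha = 10`, `k = 10`, `I2` and nearest neighbours reaches
a cross-validated weighted F1 above 0.9, and at strength 0 it scores at
chance (for balanced two-class problems and small test folds, chance-level
weighted F1 sits somewhat below 0.5 because degenerate folds are penalised
by the harmonic mean).

What the generator does *not* emulate: rearing/grooming and other
non-positional behaviour, day-night or habituation drift across sessions,
subject-specific idiosyncrasies beyond random seed, and tracking noise or
dropouts. Passing tests therefore demonstrate that the pipeline recovers
planted repetitive structure of realistic scale — not that it would attain
the same scores on any particular real cohort.

## Numerical and design choices

- Problem sizes in the tests are chosen to keep the whole suite around a
  minute on one core: property suites use 1000 random sequences up to
  length 500; the end-to-end check uses 10 subjects per class with
  30-minute sessions (60 ten-minute segments).
- All randomness is seeded; cohort generation and fold assignment restore
  the caller's RNG state.
- `paa` on a constant series, single-frame trajectories, candidate pools
  smaller than `k` (all returned, with a warning), motifs containing
  symbols absent from a series (count 0), and degenerate pooled data with
  zero variance (an error in `normal_quantile` mode) are all handled
  explicitly and tested.
- One grammar is induced per segment and candidate frequencies are summed
  across the segments of a class; inducing a single grammar per
  concatenated class corpus is the untested alternative, rejected here
  because it would create artificial motifs spanning segment boundaries.
- Known limitations: Sequitur's derivation counts under-count expansions
  that straddle rule boundaries (see above); motif inventories are
  arena-specific, so models should not be transferred across layouts; and
  the MLP is the least stable of the four classifiers on small feature
  matrices, as its own literature warns.

## A short session

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_spec(n_per_class = 4, session_s = 600,
                                      seed = 42))
segs <- segment_set(cohort, duration = 200)
fit <- kmotif(segs, w = 15, alpha = 8, k = 5, measure = "I2")
summary(fit)
kmotif_cv(segs, w = 15, alpha = 8, k = 5, measure = "I2",
          classifier = "k_nearest_neighbours", folds = 5, seed = 1)
```
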