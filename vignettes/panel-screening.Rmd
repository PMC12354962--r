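---
title: "Methods: mutual-information ranking and Monte Carlo panel evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutual-information ranking and Monte Carlo panel evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`panelscreen` estimates how well gene panels separate two labeled groups
of samples in an expression matrix, before any heavier downstream
analysis is committed to. This vignette is the package's own account of
the statistical machinery, the choices that were genuinely open, and
what the synthetic controls do and do not demonstrate.

## The data model

Everything operates on a dense samples × genes matrix with one binary
label per sample (`labeled_matrix`). Expression units are whatever the
user provides — raw counts, CPM, integrated values. The package never
normalizes, batch-corrects, or imputes: those decisions interact with
the biological question, and a central use of the tool is to *compare*
preprocessing variants by the predictive signal they retain. The only
hard requirements are finite values (NA/Inf is an error, never silently
repaired) and unique gene names (duplicates are suffixed `.1`, `.2`, …
in file order, with a warning).

Sparse h5ad inputs (CSR/CSC) are densified on load. This simplifies the
numerics — binning, min-max scaling and network training all want dense
arrays — at a memory cost proportional to `n_samples × n_genes`;
`log_peak_memory()` reports the session's footprint.

Group labels are encoded by the order of the requested annotation
values: first value → 0, second → 1. When no order is meaningful,
lexicographic order is the deterministic fallback. This keeps the
encoding a pure function of the inputs, so reruns and caches agree.

## Mutual-information ranking

For each gene the expression range is cut into equal-width bins and the
plug-in mutual information between the bin assignment and the label is
computed in bits. Three design points matter:

**Bin count.** Sturges' rule, `ceil(1 + log2 n)`, with a floor of 2.
Equal-width binning with a deliberately low bin count trades resolution
for support — in zero-inflated single-cell data most genes concentrate
mass near zero, and fine bins would be empty or nearly so. An explicit
`n_bins` overrides the rule when more resolution is wanted.

**Support guard.** An MI estimate is trusted at a bin count only when
*every* bin — including empty ones — holds at least
`min_datapoints_per_bin` samples (default 10). Requiring support in
empty bins is intentional: an empty interior bin means the histogram is
effectively coarser than its nominal bin count, and plug-in MI on sparse
histograms biases upward. On failure the bin count is decremented and
retried down to 2 bins; a gene that fails even there is scored 0 and
flagged `supported = FALSE` rather than dropped, so the ranking always
covers all genes and downstream code can still inspect the flag. The
alternative — skipping unsupported genes outright — would silently
shrink the gene universe on heavily zero-inflated data.

**Determinism.** Ties are broken by ascending column index; tiny
negative MI from floating-point cancellation is clamped to exactly 0;
cache files store 17 significant digits so a cache round trip is
value-exact. The cache is keyed by a hash of the configuration, a
present-but-corrupt cache is an error instructing deletion (silent
recomputation would mask data-management mistakes), and a missing cache
is simply a miss.

User-defined panels bypass MI entirely: `mock_ranking()` assigns every
listed gene the placeholder score 1 (in user order, all-or-nothing name
resolution) so custom panels flow through the identical classification
and search code paths as ranked ones.

## Panel evaluation: Monte Carlo cross-validation

A panel's predictive power is the distribution of test balanced accuracy
over repeated random splits (default `number_sweeps = 10`): per sweep, a
stratified draw holds out `test_fraction = 0.2` of each class, per-gene
min-max scaling is fitted on the training split only (test values are
clipped into [0, 1]; train-constant genes map to 0), and a classifier is
fitted and scored. Balanced accuracy — the mean of per-class recalls —
is used throughout so class imbalance cannot inflate results; 0.5 is
chance for any prevalence. Stratification keeps both classes present on
both sides, which balanced accuracy requires to be well defined.

The classifier is a single-hidden-layer perceptron (default width 100,
rectified-linear hidden activation, logistic output) trained by
full-batch Adam on binary cross-entropy with a small L2 penalty
(`alpha = 1e-4`, biases exempt). Training stops at `max_iterations =
500` epochs or earlier when the loss has improved by less than `1e-4`
for 10 consecutive epochs. Because full-batch training takes exactly one
gradient step per epoch, the step size default is 0.01 — larger than
typical minibatch settings — so panel-sized problems reach their loss
plateau well inside the epoch cap. All weight initialization and data
shuffling derive from `sweep_seed = base_seed + sweep_index`, making
every evaluation bit-reproducible; random-baseline gene draws use an
offset seed so gene sampling and splitting are decoupled.

Four selection modes share this engine: top-ranked genes (`SELECTED`),
user panels (`CUSTOM`), size-matched random draws from the non-constant
pool redrawn each sweep (`RANDOM`), and all non-constant genes
(`ALL_GENES`). An optional external hold-out matrix supports the
anti-circularity pipeline: split first, rank and train inside the
training part only, evaluate every sweep on the untouched hold-out.

## Subset search

Small candidate pools (at most `greedy_threshold = 10` genes) are
searched exhaustively over all `2^n − 1` non-empty subsets; pools of 20
or more would exceed a million subsets and are rejected outright with a
pointer to greedy mode. Larger pools use greedy forward selection:
starting from the empty panel, every one-gene extension is evaluated and
the best extension by mean test balanced accuracy is accepted, stopping
when the gain is at most `improvement_tolerance` (default 0: strict
improvement) or `max_panel_size` is reached. Two refinements are off by
default: beam search keeps the `beam_width` best partial panels per
depth, and swap refinement tries all single in-panel/out-of-panel
exchanges after each acceptance, applying the best strictly improving
swap to a fixed point (capped at panel-size rounds). Ties anywhere are
resolved toward lower-ranked candidate positions, so searches are fully
deterministic.

Every panel's evaluation is seeded by a 32-bit hash of its sorted gene
names folded with the run seed. This has two consequences worth
spelling out: results are independent of evaluation order and thread
count (`num_threads` is purely a throughput knob), and when greedy and
exhaustive searches visit the same subset they produce bitwise-identical
evaluations, which makes greedy-vs-exhaustive comparisons exact rather
than statistical. The returned map contains every panel evaluated along
the way, keyed by the subset in candidate-pool order.

## Synthetic controls

Two generators provide the study conditions for testing, defaulting to
200 samples per group and 500 genes:

- `generate_marker_dataset()` plants `n_informative` markers (default 5)
  on a log-normal background (gene-specific log-means, so magnitudes
  span realistic ranges) by shifting the group-1 mean of each marker by
  `effect_size` within-group standard deviations (default 2; 4 makes a
  marker essentially separable). Dropout zeroes entries independently
  with probability `dropout_probability`; the default 0.1 is a mild
  zero-inflation rate in line with deeply sequenced full-length
  protocols, chosen so the support guard is exercised without dominating
  the signal.
- `generate_null_pair()` draws one base group and duplicates it,
  perturbing the copy with zero-mean Gaussian noise whose per-gene SD is
  `noise_fraction` (default 0.01, i.e. 1%) of that gene's base SD. The
  relative-to-SD reading of "1% noise" was chosen over
  relative-to-mean or absolute scales because it perturbs every gene
  equally in information terms; an absolute option exists but is not the
  default.

**What the null pair shows — and a warning about it.** The null pair
carries no group-level signal, so a pre-analysis run on it must not
report separability; the package's tests assert exactly that. It is
worth understanding, however, that this construction is *adversarial*
for memorizing classifiers: every sample has a near-duplicate twin of
the opposite label, and a model that partially memorizes its training
set will predict, for a test sample whose twin was in training, the
twin's — i.e. the wrong — label. Test accuracy then lands *below*
chance, an anti-generalization artifact of the paired design rather
than evidence of signal. With the default early stopping the network
usually halts at its loss plateau before much memorization occurs, but
longer, slower training pushes results visibly under 0.5. In practice:
treat any all-gene accuracy at or below the chance band as "no usable
signal"; sub-chance values on duplicated-and-perturbed controls are a
property of the construction, not of the data-generating biology.

These generators emulate effect size, skewness, and zero-inflation.
They deliberately do not emulate library-size variation, batch
structure, cell-cycle covariates, or gene-gene correlation; a passing
control therefore demonstrates the machinery's calibration, not
robustness to confounding in real data.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated
data at the default scale (400 samples × 500 genes) or smaller; subset
searches use pools of 3–5 candidates so exhaustive enumeration stays in
the tens of panels. The MI estimator is verified against a brute-force
double-sum oracle to 1e-12 over a thousand random joint tables, and the
discretizer's conventions (half-open bins, right-closed last bin,
constant vectors to bin 0) are asserted directly. Degenerate inputs are
defined, not accidental: single-sweep standard deviations report 0,
constant genes are excluded from classification pools, and splits that
would empty a class raise errors instead of producing undefined
metrics.

## Limitations

Balanced accuracy measures association, not causation; a highly
predictive panel is a hypothesis, not a mechanism. Repeated evaluation
of many subsets on the same data risks selection bias — the hold-out
pipeline exists for exactly that reason and should be preferred when a
panel's accuracy will be reported as a claim. Training accuracy far
above test accuracy across panel sizes is the overfitting signature to
watch for in the size-benchmark plots. Finally, the perceptron is
intentionally a fixed, simple architecture: the goal is a comparable
yardstick across panels, not the best possible classifier for any one
of them.
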