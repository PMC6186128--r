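---
title: "Methods: bootstrap-aggregated co-expression network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bootstrap-aggregated co-expression network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bclr)
```

## The problem

Co-expression networks inferred from transcriptional compendia are
surprisingly sensitive to the exact set of conditions used: removing a
modest fraction of the expression profiles can change a large share of the
inferred edge confidences, which then propagates into the biological
interpretation. `bclr` implements a resampling remedy — condition-level
bootstrap aggregation — together with the measurement apparatus needed to
ask whether it actually helps: stability against data removal, accuracy
against a partial regulator–target standard, and a pathway-level overlap
measure.

Throughout, a **condition** is one expression profile arising from one
perturbation (growth condition, genotype, time point). Conditions are the
resampling unit; genes are never resampled.

## Inference

### B-spline mutual information

Pairwise dependence is scored by a soft-binning mutual information
estimator. Each gene's profile is affinely rescaled onto the domain of a
clamped uniform B-spline basis with `num_bins` functions of order
`spline_order`. Every sample then receives fractional membership weights
over the bins (the basis values, which are nonnegative and sum to one), so
that

* marginal bin probabilities are sample means of the weights, and
* the joint distribution of a gene pair is the sample mean of the weight
  outer products.

MI is the usual sum `Σ p(a,b) log2(p(a,b) / (p(a) p(b)))` over bins with
positive joint mass. Because each sample's weights sum to one, the joint's
marginals coincide exactly with the marginal estimates; the estimate is a
Kullback–Leibler divergence and hence nonnegative (tiny floating-point
negatives are clamped to zero). Compared with hard histogram binning, the
spline weights smooth bin boundaries, which matters at the small sample
sizes that aggressive condition subsampling produces.

One subtlety worth recording: with soft binning the joint distribution of a
profile *with itself* is not diagonal (a sample sits in up to
`spline_order` bins at once), so the self-information `MI(x, x)` equals
`2·H(x) − H(x, x)` computed from the same weights, which is *below* the
marginal entropy `H(x)`. Only at `spline_order = 1` (boxcar weights, i.e.
hard binning) does `MI(x, x) = H(x)` hold exactly. The test suite pins both
identities. Diagonal self-MI values are kept out of all background
statistics, so this has no effect on inferred networks.

Defaults are `num_bins = 10`, `spline_order = 3`, and base-2 logarithms
(bits). When a subsample has fewer conditions than bins, the bin count is
reduced to the sample count (and, if necessary, the spline order to the bin
count) with a warning rather than an error: fraction sweeps deliberately
reach regimes of only a handful of conditions, and those runs must complete.

### CLR background correction

Raw MI favours high-entropy genes and hubs. The context likelihood of
relatedness (CLR) transform compares each `MI(i, j)` with the background of
gene *i*: the mean and standard deviation of `MI(i, k)` over all partners
`k ≠ i`. The one-sided z-score `z_i = max(0, (MI(i,j) − μ_i) / σ_i)` is
combined across both endpoints as `score(i, j) = sqrt(z_i² + z_j²)`. Two
numerical choices are fixed here:

* the background uses the *population* (divide-by-n) standard deviation
  over the n−1 partners, matching the common reference behaviour of the
  algorithm; and
* `σ_i = 0` (a perfectly flat background row) defines `z_i = 0` rather
  than propagating an infinity.

Because z-scoring is invariant to positive rescaling of the MI matrix, the
CLR scores do not depend on the logarithm base; the suite verifies this at
rescalings ×0.5 and ×3 and between bases 2 and *e*.

### Pearson alternative

`infer_pearson()` scores pairs by |Pearson r|. The absolute value is a
deliberate design decision: edge weights are nonnegative confidences that
get *averaged* across bagging iterations, and signed averaging would let an
anticorrelated edge cancel a correlated one. The synthetic generator draws
regulatory weights with random signs precisely to keep this choice honest —
anticorrelated true edges must be recoverable. Constant genes receive zero
scores with a warning instead of NA.

## Bootstrap aggregation

`bag_network()` repeats, for `iterations` rounds (default 200): draw
`max(2, floor(fraction × n_conditions))` conditions uniformly **without
replacement**, infer a constituent network from the subset, and fold it
into a running mean of edge weights. Strictly speaking this is the random
subspace method over the condition axis rather than a classical bootstrap
(no condition repeats within an iteration), but the field's usual name for
the procedure is feature bootstrap aggregation, and the consensus is the
plain arithmetic mean of the constituents — no per-constituent rank
normalisation, because constituent scores are meant to be used as
generated.

Convergence is tracked as the MAE between consecutive running means (the
first entry is the distance from the zero matrix) and optionally as the
AUPR of the running mean against a standard. Both traces are recorded;
`convergence_summary()` judges convergence on the MAE trace, since that
criterion needs no standard. For a running mean the update magnitude is
bounded by `max constituent entry / t`, so the trace decays as O(1/t); the
suite asserts this bound and the acceptance checks require the update at
iteration 50 to sit below 20% of its iteration-2 value.

Reproducibility contract: one master seed deterministically derives a
sub-seed per (iteration, retry attempt), so results are independent of any
execution schedule, and a degenerate subsample (e.g. inference failure on
an all-constant draw) is retried with a fresh draw up to 10 times before
aborting.

## Evaluation

**Stability** is the MAE between two score matrices over all distinct gene
pairs (upper triangle). It is computed over *all* pairs, not just standard
pairs, because stability is defined against the parent network, not the
standard; `mae()` therefore never touches an edge standard.

**Accuracy** is the area under the precision–recall curve against a partial
directed standard. The standard lists directed (regulator, target) pairs
labelled 0/1; every unlisted pair is masked and never enters the
evaluation. Since CLR and Pearson networks are undirected, each directed
pair is scored by the undirected edge score — if both directions of a pair
appear with conflicting labels, both are evaluated with the same score,
faithful to casting the standard as a dense directed matrix with NaN for
absent entries. AUPR uses step-wise (rectangular) integration over distinct
thresholds with all tied scores entering at one threshold: no
interpolation, no optimistic bias, and permutation-independence under ties.
An uninformative ranking scores the prevalence (positives over evaluated
pairs) up to a small, well-understood positive finite-sample bias of
average precision.

**Functional edge overlap (FEO)** is, among edges whose both endpoints are
annotated, the fraction whose category sets intersect. Edges touching an
unannotated gene are ignored; if no edge survives that filter the ratio is
*undefined* and returned as `NA`, never as 0.

**Statistics.** Method comparisons use Welch's two-sided t-test (unequal
variances, Welch–Satterthwaite degrees of freedom) via `stats::t.test()`;
p-values are reported raw, with no multiple-testing correction. Replicate
summaries use a Student-t confidence interval (default level 0.99), chosen
because experiment curves rest on few replicates per setting — 10 by
default — which is too few for a normal interval.

## Experiment harnesses

All condition-axis interfaces speak in the fraction of data **remaining**
(0.9 = 10% removed); a single canonical axis prevents off-by-complement
bugs.

* `condition_removal_experiment()` infers a parent network from all
  conditions, then repeatedly (default 10 repeats per fraction) subsamples,
  re-infers, and records MAE to the parent and, optionally, AUPR — both on
  the *same* subset per repeat, so the metrics are paired. Repeat seeds
  derive from (master seed, fraction index, repeat index), so extending the
  fraction grid never perturbs existing replicates.
* `subsample_sweep()` maps subsampling fraction to consensus AUPR on the
  full condition set, with the non-bagged method's AUPR recorded once as a
  baseline. There is no stability axis here: each consensus is its own
  parent.
* `select_fraction_by_stability()` implements the recommendation for
  studies without a usable standard: build a bagged parent per candidate
  fraction, measure each candidate's condition-removal curve against its
  own parent, and pick the candidate with the most stable curve, finally
  returning that candidate's full-data consensus. "Most stable" is not
  formally pinned down by the procedure's description, so the objective is
  selectable: mean MAE across the curve (default), maximum MAE, or
  normalised area under the curve. Ties go to the smaller fraction. Each
  repeat draws fresh bagging subsamples rather than reusing them across
  candidates.

## Synthetic data generator

The generator emulates a perturbation compendium at desk scale with a
linear-Gaussian model: each condition is an independent perturbation in
which regulators are standard-normal, each regulated target is the weighted
sum of its parents plus Gaussian observation noise, and parentless targets
are unit-variance noise. Regulators are included among the observed genes
so regulator–target AUPR is computable exactly as with real benchmark
compendia. Edge weights have magnitude uniform in a configurable range and
random sign. The partial standard takes all true edges as positives and a
configurable fraction of non-edges as negatives, leaving the rest masked,
so evaluation code always exercises the masking path. Annotations assign
each regulator a category and let targets inherit a parent's category with
probability 0.8, mimicking pathway co-membership.

For a single-parent target with weight *w* and noise σ, the model predicts
|Pearson r| = |w| / sqrt(w² + σ²); the suite uses this closed form as an
oracle (r ≈ 0.9988 at w = 2, σ = 0.1) and the noiseless case gives |r| = 1.

What this generator does **not** emulate — and what passing tests therefore
do not establish about real data: regulatory dynamics and saturation
(no ODEs), time-series or batch structure, indirect-effect cascades beyond
linear mixing, heavy-tailed expression distributions, and the heterogeneous
quality of curated standards. Results on real compendia depend on all of
these.

### Study conditions and problem sizes

The default synthetic scenario used by the recovery and convergence checks
is 10 regulators, 90 targets, edge density 0.05, 200 conditions, and noise
sd 0.5 with a fully labelled standard; the stability-curve checks use a
30-gene (5 regulator, 25 target, density 0.1) compendium over fractions
0.2–0.9 with 10 repeats; convergence is assessed at subsampling fraction
0.5 over 50 iterations. These sizes were chosen once as the smallest
compendia on which every mechanism under test (masking, background
statistics, ensemble averaging, curve aggregation) operates in its intended
regime while keeping the whole suite quick on a single core.

## Known limitations

* The consensus averages raw CLR z-score-derived confidences across
  constituent networks of differing subsample sizes; no attempt is made to
  calibrate scales across iterations, mirroring the use-as-generated
  convention.
* FEO depends on annotations keyed by the same identifiers as the
  expression matrix; no identifier mapping layer is provided.
* MAE compares score matrices entry-wise and is therefore only meaningful
  between networks produced by the same scoring method and configuration.
* The B-spline MI estimator is a density plug-in; it is consistent but
  biased at small n, and no bias correction is applied (the CLR z-scoring
  absorbs gene-wise bias to first order).
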