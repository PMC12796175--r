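---
title: "Dual quality control for plantar pressure maps: normative statistical mapping and an explainable convolutional classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual quality control for plantar pressure maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantarqc)
```

## The problem

Plantar pressure recordings — 2D maps of vertical force under the foot —
routinely contain technically corrupted samples: incomplete captures
(missing forefoot or heel), frames holding both feet at once, maps recorded
upside down, and left/right annotations attached to the wrong foot.  In
multicenter datasets these outliers are too numerous to screen by hand.
`plantarqc` implements two automated detectors over standardized
64×64 maps normalized to `[0, 1]`, plus everything needed to compare them:
a synthetic data generator, a registration pipeline, a nested grouped
cross-validation harness and survey-analysis utilities for expert ratings
of the two explanation styles.

Throughout, label 0 marks valid samples and labels 1–4 the four outlier
categories: general acquisition error, double-foot capture, inverted
orientation, incorrect side annotation.  Grids follow a fixed orientation
convention: row 1 is distal (toes), row 64 proximal (heel), columns run
left to right in the image plane.

## The normative statistical map

The first detector treats outlier detection as normative inference.  All
valid maps of one laterality are registered to a per-side template and
stacked into a cohort; a test map (registered the same way) is scored
pixel by pixel with a two-tailed empirical p-value

$$
p = \min\!\Big(1,\; 2\min\big(p_\text{high},\,p_\text{low}\big)\Big),
\qquad
p_\text{high} = \frac{1 + \#\{x_i \ge t\}}{n + 1},
\quad
p_\text{low} = \frac{1 + \#\{x_i \le t\}}{n + 1},
$$

where $t$ is the test intensity and $x_1,\dots,x_n$ the cohort intensities
at that pixel.  The add-one correction keeps p-values strictly positive,
and ties count toward both tails, so fully tied background pixels get
$p = 1$.  A consequence worth knowing: the smallest attainable p-value is
$2/(n+1)$, so a forming threshold below that (e.g. 0.01 with $n = 150$)
cannot mark any pixel suprathreshold — cluster detection requires
$\alpha_\text{forming} > 2/(n+1)$.

Deviant pixels ($p < \alpha_\text{forming}$) are grouped into connected
clusters (8-connectivity by default; configurable to 4 — the choice is a
convention, diagonal contact counts as contiguity under the default) and
filtered by a minimum size `min_cluster`.  Family-wise error control uses a
permutation null of maximum cluster sizes: each of 1000 iterations draws
one cohort member, scores it against the remaining members (leave-one-out),
and records its largest surviving cluster.  A test cluster is significant
only if its size *strictly exceeds* the nearest-rank $(1-\alpha_\text{FWE})$
percentile of that null; a map is an outlier when at least one significant
cluster remains.  The leave-one-out resampling scheme is the package's
resolution of how to "permute" a one-vs-cohort test: it preserves
exchangeability between the pseudo-test draw and the true test statistic,
which is what makes the per-map false-positive rate track
$\alpha_\text{FWE}$ (the test suite checks this on 500 held-out null maps).
Background pixels are deliberately *not* masked out of the analysis:
double-foot and inverted maps put pressure where the cohort has none, and
those pixels are exactly where their evidence lives.

The two free parameters, $\alpha_\text{forming} \in [0.01, 0.05]$ and
`min_cluster` ∈ 0..30 px, are tuned by randomized search in the inner loop
of the cross-validation, scored by binary F1 on the validation split, with
ties broken toward the more conservative candidate (larger `min_cluster`,
then smaller $\alpha_\text{forming}$).  One permutation null is computed
per model and configuration and reused across the test samples of a fold;
it is recomputed whenever the tuner changes the configuration.

Side-swapped samples (label 4) are tested against the cohort of their
*annotated* side — that is the only mechanism by which a pure label error
can produce a signal in this branch, and it is also why the branch misses
many of them: left and right feet differ mostly in the arch region, so the
deviation is localized and often below the cluster threshold.

## Registration

The normative branch needs pixel-level anatomical correspondence.  Each
map is aligned to a per-side reference template by a bounded affine
transform (rotation about the canvas centre, isotropic zoom, translation)
minimizing the mean squared intensity error, optimized with L-BFGS-B under
bounds of ±30°, ±10 px and zoom ∈ [0.8, 1.25].  Gradients are numerical
(step 10⁻³): the objective is piecewise smooth under bilinear
interpolation and this keeps the optimizer independent of the interpolant.
The template itself is the pixel-wise mean of centroid-aligned valid maps
of that side, re-normalized to maximum 1 (an exemplar mode is available;
averaging was chosen because it suppresses subject idiosyncrasies).  An
optional multi-start (±10°, ±5 px) guards against local minima when
inputs may be far from the canonical pose; inside the fold pipeline maps
start near it, so the identity start is the default there.  Alignment is
quantified by the intersection-over-union of the binarized (pressure > 0)
footprints.  Registration serves only the normative branch — the
classifier consumes unregistered grids.

## The convolutional classifier

The second detector is a five-class convolutional network over the
unregistered 64×64 maps with the integer side label as a second input:

* three blocks of two 3×3 convolutions (padding 1) with batch
  normalization and ReLU, followed by 2×2 max-pooling and channel dropout
  (0.25); filter counts 32, 64, 128, spatial size 64 → 32 → 16 → 8;
* the flattened 128·8·8 = 8192 features concatenated with an
  8-dimensional embedding of the side label (8200 total);
* a head of one 256-unit linear layer with batch normalization, ReLU and
  dropout 0.5, then the 5-class output layer.

The laterality embedding is what makes label-4 outliers learnable at all:
the map alone is a perfectly valid foot, and only the (map chirality,
side label) pair is inconsistent.  Training uses Adam at learning rate
0.001, cross-entropy weighted inversely to training class frequency,
class-balanced epoch sampling (both imbalance measures are applied, with
switches to ablate either), early stopping after 10 epochs without
validation-loss improvement, and retention of the checkpoint with the
lowest validation loss.  Two refinements make the early-stopping rule
well behaved numerically: an improvement only resets the patience counter
when it exceeds `min_delta` (10⁻⁴ on the loss scale) — otherwise
vanishing late-training fluctuations postpone the stop indefinitely —
and the retained checkpoint is still simply the lowest-validation-loss
epoch.  Chirality-versus-label learning (the valid/side-swap boundary) is
the slowest part of optimization: it consolidates abruptly after a few
hundred optimizer steps, which is why the default batch size is 16 — on a
single CPU, smaller batches buy twice the update count per epoch at
nearly identical cost per epoch, and the consolidation arrives several
epochs earlier.  Per-fold scalar standardization statistics (mean
and SD over all training pixels) are computed on the training partition
only and reused at prediction time, after the `[0, 1]` intensity
normalization of preprocessing — computing them on the normalized scale is
the only ordering under which both normalizations can coexist.  The whole
network is implemented in single-precision compiled code (im2col + BLAS
gemm); all randomness (initialization, sampling, dropout) flows from one
integer seed, so training is reproducible bit-for-bit.

Unstated-by-design hyperparameters were fixed once at standard values:
batch size 16 (see above), max 200 epochs (callers pass tighter caps),
conv dropout 0.25, head width 256, head dropout 0.5, He initialization,
standard-normal embedding initialization.

## Shapley-additive attributions

Per-pixel explanations back-propagate *multipliers* from the target-class
logit against a background set (default 100 training samples): linear
layers and inference-mode batch normalization propagate multipliers
exactly, ReLU uses the rescale rule
$m = (\mathrm{ReLU}(z_x) - \mathrm{ReLU}(z_r)) / (z_x - z_r)$, and each
max-pool window routes its output delta to the input with the largest
absolute delta.  Every rule conserves the layer delta, so for each
background reference the attributions (pixels plus the side-embedding
term) sum *exactly* to the difference between the sample's and the
reference's target logit; averaging over the background preserves the
identity against the mean background logit.  The tests assert this within
1% relative tolerance (slack for single-precision accumulation only).

For display, attributions below 20% of the maximum absolute value are
zeroed, the map is smoothed with a bilateral filter (diameter 5 px, range
sigma 0.1, spatial sigma 2 px — chosen to be mild at 64×64), and overlaid
as a diverging blue (supporting the predicted class) / red (opposing)
heatmap.  The three-panel figure shows the raw grayscale map, the
normative decision with green contours around significant clusters, and
the attribution overlay; a survey-parity mode reduces captions to
valid/outlier so neither branch reveals more label detail than the other.

## Synthetic data: what it emulates and what it does not

No public plantar pressure corpus with this outlier taxonomy exists, so
the package ships a generative stand-in, and it is first-class, tested
code.  A subject draws anatomical parameters (overall size and width,
heel ellipse, five metatarsal and five toe blobs with a medial-to-lateral
intensity gradient, a lateral midfoot band leaving a pronounced medial
arch void, all as Gaussian intensity bumps); the left-foot template is
rendered from these and the right foot is its exact column mirror.  Each
sample then receives a placement jitter (rotation SD 2°, shift SD 1.5 px,
zoom SD 3% — mirror-covariant, so left/right symmetry is exact at zero
noise) and multiplicative intensity noise (SD 0.10), and is re-normalized.
Dynamic-condition maps get a mild distal load accentuation.  These
parameters were chosen once so that the rendered maps satisfy the
qualitative description experts give of real maps — heel and metatarsal
maxima, arch void, connected footprint occupying 10–45% of the canvas —
and are not revisited (the rendered footprints occupy 28-49% of the
canvas across subjects).

The four outlier generators follow the published recipes exactly:
forefoot crops zero the distal fraction drawn uniformly from
[0.45, 0.55] of rows, heel crops the proximal [0.60, 0.70]; double-foot
composites downscale a same-subject left/right pair to 32×32 tiles placed
in diagonally opposite quadrants (which foot goes upper-left is random,
each tile jittered 0–2 px in a random cardinal direction, laterality
assigned at random); inversion reverses rows (a `rot180` switch also
mirrors columns — the literal row flip is the primary reading, the
half-turn the alternative); side swaps toggle the label and keep the grid
bit-identical.  Crops are sampled uniformly within their bands because no
distribution was specified.  Augmentation tops each category up to a
target count (500 by default) from randomly chosen valid sources, and
derived samples inherit their source subject so grouped cross-validation
can never separate them from it.

The default study-scale dataset uses 200 subjects × 2 sides × 2 conditions
= 800 valid samples and 500 outliers per category (2800 samples), mirroring
the published cohort proportions (798 valid, 2000 outliers).  What the
generator does *not* emulate: pathological but valid morphologies (hallux
valgus, flat foot) that drive false positives on real data, sensor-specific
noise structure, footwear artifacts, and stride-to-stride dynamics.
Passing tests on synthetic data therefore demonstrate that the machinery
is correct and that the two branches rank as published under clean
conditions; they do not certify real-data accuracy.

## Evaluation protocol

The comparison uses nested grouped stratified cross-validation: five outer
folds assign whole subjects (with all their samples, including derived
synthetic ones) by a greedy deficit-filling heuristic that balances label
counts across folds — exact grouped stratification is combinatorially
hard, and the greedy assignment keeps per-fold label proportions within a
few points of global.  Within each outer training set, an 80/20 grouped
inner split (same heuristic, two bins with capacity targets) provides the
tuning/early-stopping validation data.  Both branches see identical
partitions.  Five-class CNN predictions are reduced to binary
(outlier = any label ≠ 0) for the head-to-head comparison; metrics are the
Matthews correlation coefficient and F1 with the outlier class positive,
reported per fold, pooled, and in a variant restricted to real-provenance
test samples (the augmentation-derived samples carry `synthetic`
provenance precisely to make this sub-report possible).  Generating all
synthetic samples once and confining them to their source subject's fold
reconciles subject-level leakage control with test folds that contain
synthetic outliers; the real-only variant is always reported alongside, so
both readings of the protocol are available.

## Survey statistics

Expert ratings of the two explanation styles (eight semantic-differential
attributes, 7-point scales, ten items per approach) are aggregated to
subject-level medians (midpoint convention), compared per attribute with a
two-sided Wilcoxon signed-rank test, and Bonferroni-corrected across the
eight attributes.  Zero differences are dropped (the classical
convention).  P-values are computed by exact enumeration of all sign
assignments up to 20 pairs — the exact conditional distribution remains
valid under ties, where the usual exact tables do not — with a
tie-corrected normal approximation beyond.  Confidence intervals of
medians use the percentile bootstrap (5000 resamples).  Post-hoc power for
a paired design approximates the signed-rank test through its asymptotic
relative efficiency versus the paired t-test (0.955): effective sample
size $n' = 0.955\,n$, noncentrality $d_z\sqrt{n'}$, two-sided critical
value from the central t with $n'-1$ degrees of freedom.  For
$d_z = 0.8$, $n = 16$, $\alpha = 0.05$ this gives 0.829.  A
Bonferroni-adjusted power figure is deliberately not computed: it depends
on the number of comparisons assumed under correction, which is ambiguous,
so the package reports only the uncorrected approximation.

## Numerical choices and degenerate inputs

* Empirical p-values use add-one correction; all-zero cohorts at a pixel
  give $p = 1$ for a zero test intensity (ties on both sides).
* The FWE threshold is the nearest-rank percentile; significance requires
  strict exceedance, so a candidate equal to the threshold is rejected.
* Registration ties between multi-starts break toward the smaller
  parameter norm; the returned fit never has a worse MSE than the identity
  start.
* `embed_to_grid` resizes bilinearly with half-pixel-centre alignment and
  re-normalizes after interpolation; it is exact on already standardized
  inputs.
* All-zero grids are rejected by `normalize_intensity` (degenerate), as is
  a zero-variance training set by `compute_fold_stats`.
* Bilinear warps clip to `[0, 1]` and fill out-of-canvas samples with 0.
* Batch normalization needs at least two samples; a trailing singleton
  minibatch is dropped.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, sized so
the full suite completes on a single CPU: 150-map cohorts with 500 null
maps and 1000 permutations for the calibration check, 100 maps for the
registration floor, and one outer fold of the 200-subject default dataset
(about 1800 training maps) for the end-to-end comparison, with the
classifier capped at 14 epochs under early stopping — on the default
dataset the five-class problem is solved well before that cap.  Unit
tests use a slimmed filter configuration (8/12/16) over the same code
paths.

## Known limitations

* The foot model is a parametric stand-in; its between-subject variance is
  plausibly narrower than reality, which makes both detectors' task easier
  than on clinical data.
* The normative branch's null calibration assumes exchangeability between
  the cohort and test maps; subject-level repeated measures in the cohort
  weaken this slightly in the full pipeline (the calibration check uses
  i.i.d. draws).
* Deformable registration, covariate-adjusted normative models and
  per-region aggregation are out of scope.
* Attribution backends other than the multiplier scheme (e.g. sampling
  approximations of Shapley values) are not implemented; the additivity
  contract is the fixed interface any replacement must satisfy.
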