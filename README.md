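# plantarqc

Automated quality control for plantar pressure maps.

Plantar pressure recordings — 64×64 maps of vertical force under the foot,
normalized to [0, 1] — accumulate technical outliers in multicenter
collections: incomplete captures with the forefoot or heel missing,
frames containing both feet, upside-down maps, and left/right annotations
attached to the wrong foot.  `plantarqc` implements and compares two
detectors for these errors:

1. **A normative statistical map.**  Valid maps of each side are affinely
   registered (angle/shift/zoom, MSE objective, L-BFGS-B under bounds) to a
   per-side template and stacked into a reference cohort.  A test map is
   scored pixel-wise with a two-tailed empirical p-value
   `p = min(1, 2·min(p_high, p_low))`,
   `p_high = (1 + #{x ≥ t})/(n + 1)`, `p_low = (1 + #{x ≤ t})/(n + 1)`,
   deviant pixels are clustered (8-connectivity), and a cluster counts as
   significant only when its size strictly exceeds the nearest-rank
   `(1 − α_FWE)` percentile of a 1000-permutation null of maximum cluster
   sizes built by leave-one-out resampling of the cohort.  The forming
   threshold and minimum cluster size are tuned by randomized search on
   the inner validation split.
2. **A five-class convolutional classifier.**  Three conv blocks
   (filters 32/64/128, two 3×3 convs each, batch norm, ReLU, 2×2
   max-pool, channel dropout) over the *unregistered* map, concatenated
   with an 8-dimensional embedding of the side label, then a
   256-unit head.  Trained with Adam (lr 0.001), inverse-frequency
   weighted cross-entropy, class-balanced sampling and early stopping on
   validation loss (patience 10).  Decisions are explained by
   Shapley-additive per-pixel attributions (multiplier back-propagation
   against a 100-sample background; the attributions sum exactly to the
   logit difference), thresholded at 20% of the maximum magnitude,
   bilaterally smoothed and rendered as a three-panel comparison figure.

Both detectors run inside a nested grouped stratified cross-validation
(5 outer folds, 80/20 inner split, subjects never straddle partitions) and
are compared by binary MCC and F1 (outlier = positive).  Because no public
dataset carries this outlier taxonomy, the package ships a tested
synthetic generator: parametric foot templates (heel/metatarsal/toe
maxima, medial arch void; right feet are exact mirrors) plus the four
published outlier transformations (bounded forefoot/heel crops,
double-foot quadrant composites, row-flip inversion, side-label swap) and
augmentation of every category to a target count.  Survey-analysis
utilities (subject-median aggregation, exact paired signed-rank tests
with Bonferroni correction, bootstrap CIs, signed-rank power via the
0.955 ARE discount) cover the expert-rating arm of the comparison.

## Worked example

Simulate a small study, run both detectors on one outer fold, and compare:

```r
library(plantarqc)

ds <- simulate_dataset(n_subjects = 40, seed = 3, target = 60)
ds
#> <pressure_dataset: 400 samples, 40 subjects>
#>   counts by label: 0=160, 1=60, 2=60, 3=60, 4=60

plan  <- make_outer_folds(ds, k = 5, seed = 1)
parts <- plantarqc:::fold_partitions(ds, plan, 1, seed = 2)

spm <- run_spm_fold(parts$train, parts$val, parts$test,
                    n_candidates = 6, seed = 1)
cnn <- run_cnn_fold(parts$train, parts$val, parts$test,
                    tc = train_config(max_epochs = 30, seed = 1))

truth <- as.integer(parts$test$manifest$label != 0)
mcc(confusion(truth, as.integer(spm$predictions$is_outlier), 0:1))
#> [1] 0.9743588
mcc(confusion(truth, as.integer(cnn$predictions$binary_pred), 0:1))
#> [1] 0.3639615
confusion(parts$test$manifest$label, cnn$predictions$label_pred)
#>       predicted
#> actual  0  1  2  3  4
#>      0 17  0  0  0 15
#>      1  0 12  0  0  0
#>      2  0  0 12  0  0
#>      3  0  0  0 13  0
#>      4  9  0  0  0  3
```

The confusion matrix shows what the comparison is designed to expose: the
classifier resolves the three structural outlier classes (crops, double
feet, inversions) perfectly even at this miniature scale, but
valid-versus-swapped-side — which requires combining foot chirality with
the side-label embedding — still confuses it with only ~250 training
maps, dragging the binary MCC down, while the tuned normative map scores
0.97 here.  The ranking flips at realistic scale: on the 200-subject
default dataset (2800 samples, the setting `scripts/acceptance.R`
recomputes) the classifier's held-out binary MCC reaches 1.0, above both
the normative branch and the 0.96 level, because the chirality/label
interaction is learned once enough subjects are seen.

Explaining one decision (the attribution heatmap plus the normative
cluster contours, side by side with the raw map):

```r
bg    <- subset_dataset(parts$train, 1:100)
s     <- get_sample(parts$test, 1)
att   <- compute_attribution(cnn$model, s, bg)

tpl   <- build_reference(parts$train, s$side)
reg   <- register_map(s$grid, tpl)
model <- normative_model(register_dataset(parts$train,
                         templates = list(L = tpl, R = tpl))$dataset, s$side)
nulls <- null_max_cluster_distribution(model, spm$config, seed = 1)
dec   <- classify_spm(reg$registered, model, spm$config, nulls)

render_triptych(s, dec, att, "triptych.png",
                cnn_label = cnn$predictions$label_pred[1])
```

A thin command-line front end is installed with the package
(`inst/exec/plantar-qc`) with `generate`, `preprocess`, `register`,
`detect` and `evaluate` subcommands over plain-directory datasets
(`manifest.csv` + one CSV grid per sample).

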