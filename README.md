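# seroarray

Autoantibody profiling from spotted protein macroarrays: image
quantification, per-antigen scoring, and serum classification.

Protein macroarrays present thousands of expressed proteins in duplicate
spots on a membrane. Probed with patient serum, each spot's darkness in
the 8-bit grayscale scan measures the serum's autoantibody reactivity
against one antigen. `seroarray` is for researchers running such
seroreactivity screens (e.g. tumor-autoantibody biomarker panels) who
need a tested, reproducible path from raw scans to classification
results — plus a synthetic-array simulator with known ground truth so
the whole pipeline can be validated without patient data.

## What it computes

**Image quantification** (`quantify_image`): correct the global scan
rotation (dark-pixel projection alignment), crop the edges, segment the
array into subgrids and spot target areas, split each area into
foreground/background by exact 1-D 2-means clustering (the darker
cluster is the spot), optionally grow areas whose spot spills over,
apply a black top-hat filter (closing with a square structuring element
minus the image) to flatten the background, and average duplicate spots
into one integer profile in 0–255 per antigen.

**Antigen scoring** (`quantile_normalize`, `antigen_auc`, `auc_table`):
profiles are quantile-normalized (all sera share the mean sorted
distribution; ties get averaged quantiles), then each antigen is scored
by the area under the ROC curve traced by sweeping thresholds over the
observed intensities:

    AUC = P(X₂ > X₁) + ½·P(X₂ = X₁),   X₁ ~ group 1, X₂ ~ group 2

so AUC = 0.5 means indistinguishable groups, AUC < 0.5 means group 1
runs higher, AUC > 0.5 means group 2 does. Antigens with AUC < 0.3 or
AUC > 0.7 are flagged informative.

**Classification** (`cross_validate`, `permutation_test`): a
linear-kernel SVM with cost C = 1, evaluated by stratified 10-fold
cross-validation repeated 10×, with quantile normalization refitted
inside every training fold (no test-set leakage). Per repetition the
pooled confusion counts give

    sensitivity = TP/(TP+FN),  specificity = TN/(TN+FP),
    accuracy    = (TP+TN)/n

reported as medians with 95% percentile intervals, plus per-serum
calibrated probability scores. A stratified label-permutation test
(class sizes preserved, full CV per permutation) provides the chance
distribution of accuracy and a one-sided rank-sum p-value.

## Worked example

Simulate a panel of 80 sera (40 per group) over 500 antigens, 10% of
them truly differential, render and re-quantify one scan, score the
antigens, and classify:

```r
library(seroarray)

cfg <- sim_config(n_antigens = 500, n_subgrid_rows = 5, n_subgrid_cols = 5,
                  spots_per_subgrid = 42, n_group1 = 40, n_group2 = 40,
                  frac_informative = 0.1, effect_size = 50, noise_sd = 10,
                  seed = 7)
sim <- simulate_profiles(cfg)

img <- render_image(sim$profiles[1, ], sim$truth$layout, cfg)
q   <- quantify_image(img, sim$truth$layout)
q
#> Quantified macroarray: 500 antigens (1000 spots), rotation corrected -0.00 deg
#>   empty spots: 0; adjusted areas: 0; overlap flags: 131
cor(as.numeric(q$profile), as.numeric(sim$profiles[1, ]))
#> [1] 0.981...

tab <- auc_table(quantile_normalize(sim$profiles), sim$groups)
head(tab[order(tab$auc), ], 3)
#>     antigen_id auc informative
#> 88       A0088   0        TRUE
#> 124      A0124   0        TRUE
#> 166      A0166   0        TRUE

cv <- cross_validate(sim$profiles, sim$groups, folds = 10,
                     repetitions = 10, seed = 7)
cv
#> Linear SVM (C = 1), 10-fold CV x 10 repetitions, positive class 'group1'
#>   median sensitivity 1.000  (95% CI 1.000-1.000)
#>   median specificity 1.000  (95% CI 1.000-1.000)
#>   median accuracy    1.000  (95% CI 1.000-1.000)

pt <- permutation_test(sim$profiles, sim$groups, n_permutations = 20,
                       seed = 7, observed = cv)
pt
#> Stratified permutation test: 20 permutations
#>   permuted accuracy: median 0.537, mean 0.537
#>   observed median accuracy: 1.000
#>   one-sided rank-sum p-value: 3.97e-06
```

Reading the output: the rendered scan is quantified back to within
r = 0.98 of the planted truth; the strongest antigens reach AUC 0 (group
1 higher, perfect separation); the cross-validated SVM separates the two
groups perfectly, while permuting the labels collapses accuracy to the
~54% chance level of a 40/40 design with this classifier — the gap is
what certifies that the classifier learned signal, not noise.

`run_pipeline(run_config(...))` composes the stages into one
reproducible run (profiles, AUC table, classification report, manifest
with checksums), and `exec/seroarray` exposes the same stages as shell
subcommands (`simulate`, `quantify`, `normalize`, `auc`, `classify`,
`run`).

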