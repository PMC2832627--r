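---
title: "Methods: from macroarray scans to serum classification"
author: "seroarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from macroarray scans to serum classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seroarray)
```

## The analysis problem

Protein macroarrays carry thousands of bacterially expressed proteins
spotted in duplicate on a membrane at known grid positions. Probing the
membrane with diluted patient serum and an anti-IgG detection step turns
each spot's darkness in the scanned image into a measure of the serum's
autoantibody reactivity against that protein. The questions this package
answers are: *how strongly does each serum react with each antigen*
(image quantification), *which antigens separate two serum groups*
(per-antigen AUC), and *how well do the full reactivity profiles
classify sera into groups* (cross-validated SVM with a permutation
control).

Because real patient sera and scans are rarely shareable, the package
includes a synthetic-array generator with known ground truth, so every
stage can be validated by injection and recovery.

## Image quantification

`quantify_image()` converts one 8-bit grayscale scan into a profile of
integer intensities in 0--255, one per antigen:

1. **Rotation correction.** Scanners introduce small global rotations
   (a few degrees at most). The angle is estimated from the dark pixels
   only: pixels darker than `median - 0.25 * (median - min)` are
   selected and weighted by their darkness; their coordinates are
   rotated by each candidate correction angle (coarse scan at 0.25
   degrees over plus/minus 5, local refinement at 0.05) and projected
   onto the row and column axes into one-pixel histogram bins with
   triangular splitting between adjacent bins. The summed variance of
   the two projection histograms peaks when the spot lattice is
   axis-aligned. Rotating *point coordinates* rather than resampling the
   image is deliberate: resampling blurs the image by an amount that
   grows with the angle near zero, which systematically biases a
   resampled-image criterion toward "no rotation". The point-projection
   criterion has no such bias; in injection-recovery runs it is exact to
   the 0.05-degree scan resolution for angles of 0.3 degrees and up on
   full-size arrays. Angles whose total shear across the image is below
   one pixel are physically indistinguishable from zero and estimate as
   zero, which is also harmless: sub-pixel misalignment does not move
   spots out of their target areas. The correction itself uses bilinear
   resampling about the image center. A constant image (no grid signal)
   is returned unchanged with a warning.

2. **Edge cropping.** A fixed margin per side (the layout's `margin`)
   removes membrane borders and rotation fill.

3. **Gridding.** The layout tiles the cropped image into subgrids and
   square spot target areas (`spot_pitch` pixels a side), each expected
   to contain exactly one spot. Coordinates are 0-based, half-open
   throughout; `segment_grid()` verifies all areas lie inside the image.

4. **Foreground/background clustering.** Within each target area,
   pixels are split into a dark foreground (the spot) and a bright
   background by 2-means clustering of the intensities. In one
   dimension the optimal 2-means partition is always a threshold split
   of the sorted values, so the package computes the *global* optimum
   exactly by scanning all splits between distinct values and
   minimizing the within-cluster sum of squares. This is deterministic
   and needs no starting values or iteration caps, and it is verified
   against a brute-force oracle in the test suite. Zero-variance areas
   have no spot: empty foreground, flagged.

5. **Spot-area adjustment** (`adjust = TRUE`, default). If the
   foreground touches the target-area border with a contiguous run of
   at least three pixels -- the chord of a disc spilling over, as
   opposed to isolated dark noise pixels -- the area is grown one pixel
   per side and re-clustered, up to five times. Growth stops, with an
   overlap flag, when the next expansion would swallow a neighboring
   spot's foreground. The flag is conservative on noisy images (it
   fires on dark noise in the growth ring); it never changes measured
   values, only marks spots for review. Adjustment is additionally
   gated on the foreground being a minority of the area (at most 45%),
   since an approximately even split is a noise partition, not a spot.

6. **Black top-hat.** The whole raw image is closed with a flat square
   structuring element and the image subtracted: dark features narrower
   than the element become bright peaks on a zero background, which
   removes background level and smooth gradients in one step. The
   element side defaults to the next odd integer at least 1.5 times the
   expected spot diameter (`default_se_side()`), so no element placement
   fits inside a spot and the top-hat response inside a spot equals its
   full depth below the local background.

7. **Spot intensity and duplicate averaging.** Each spot's intensity is
   the mean of the top-hat image over its foreground pixels (foreground
   from the *raw* image, intensity from the *processed* image). The two
   replicate spots of an antigen are averaged and rounded half-up to an
   integer in 0--255; a missing replicate is dropped with a flag, two
   missing replicates yield 0.

On noise-free, unrotated synthetic renders this pipeline recovers every
planted spot depth within one intensity unit (exactly, in practice); at
noise sd 10 and 1 degree rotation the recovered profile correlates with
truth at r = 0.98 or better.

## Normalization and per-antigen AUC

**Quantile normalization** (`quantile_normalize()`) forces every serum
to share the reference distribution, defined as the mean of the sorted
per-serum vectors, removing array-level effects (exposure, serum
concentration) while preserving within-serum ranks. Tied values --
guaranteed with integer 0--255 data -- receive the mean of the reference
quantiles they span. One consequence worth stating plainly: a serum
*with* ties maps onto averaged quantiles rather than the exact reference
multiset, so "all sorted rows identical" and idempotence hold exactly
only for tie-free data; for tied data the deviation is bounded by one
reference spacing. The fit/transform split (`qn_reference()` /
`qn_apply()`) lets the reference be learned on training sera only,
which the classifier uses to avoid test-set leakage.

**AUC** (`antigen_auc()`): every observed intensity serves as a
candidate threshold; sensitivity and specificity are computed at each
threshold with group 2 as the positive class, and the area under the
resulting ROC curve is taken by the trapezoidal rule. This equals the
probability that a random group-2 serum exceeds a random group-1 serum
with ties counted one half -- the midrank Mann-Whitney statistic -- and
the two routes are checked against each other on 10,000 random
instances in the tests. Orientation: AUC below 0.5 means group 1 runs
higher, above 0.5 means group 2 does; `antigen_auc(g1, g2)` and
`antigen_auc(g2, g1)` sum to 1. An antigen is flagged *informative*
when its AUC is strictly below 0.3 or strictly above 0.7.

A caveat that the test suite demonstrates as a property: when a
*large* fraction of antigens (around 10%) shifts in one direction in
one group, quantile normalization's rank remapping pushes that group's
remaining antigens the other way, biasing null antigens' AUCs away
from 0.5. This is the usual compositional artifact of
distribution-matching normalization, not an implementation defect; the
informativeness rule is well calibrated when differential antigens are
a small fraction of the panel, which is the assumption the
normalization itself makes.

## Classification protocol

`cross_validate()` evaluates a soft-margin linear-kernel SVM with cost
C = 1 (libsvm via e1071) by stratified 10-fold cross-validation,
repeated 10 times with re-drawn folds:

- **Stratified folds.** Class proportions are preserved per fold; with
  unstratified folds a small class (the study designs here go down to
  18 sera) can vanish from a fold entirely. Fold assignment is keyed on
  serum identity, so results are invariant under row reordering.
- **Per-fold normalization.** The quantile reference is fitted on the
  nine training folds and applied to the held-out fold
  (`normalize = "fold"`, default; `"global"` is available for
  comparison). A leakage probe in the tests verifies that perturbing a
  held-out serum cannot move any other serum's score.
- **Pooled counts.** Per repetition, fold confusion counts are pooled
  and converted once to sensitivity = TP/(TP+FN), specificity =
  TN/(TN+FP) and accuracy; pooling is stabler than averaging per-fold
  rates when folds hold only a few sera of a class. Medians and 95%
  percentile intervals are taken over the 10 repetition values.
- **Decision scores.** Per fold, a logistic calibration of the SVM
  decision values is fitted on the training sera and applied to the
  held-out sera, giving probability-like scores in [0, 1]; per-serum
  scores are averaged over repetitions and classified at 0.5. The
  calibration is a plain binomial GLM -- deterministic, unlike
  calibrations that re-partition the training data internally.
- **Determinism.** One top-level seed; repetition and permutation seeds
  are derived from it, so reports reproduce bit-for-bit.

`permutation_test()` guards against overfitting: class labels are
permuted (class sizes preserved -- stratified), and a full 10-fold CV
is run per permutation. With balanced classes and no signal the
permuted accuracy centers near 50%. With unbalanced classes it centers
near the class-prior chance level p^2 + (1-p)^2 (about 53.4% at 80 of
127), and in practice slightly above it, because a high-dimensional
interpolating SVM leans toward the majority class. True-label
repetition accuracies are compared against the permutation accuracies
with a one-sided Wilcoxon rank-sum test.

## The synthetic generator

`simulate_profiles()` and `render_image()` emulate what the analysis
assumes about the data-generating process, with known truth:

- **Sparse reactivity.** Per-antigen baseline spot depths are drawn
  from an exponential distribution (default mean 20 of 255): most
  antigens react weakly, a few strongly, as in seroreactivity screens.
  The intensity scale is the only thing the assay fixes (8-bit scans).
- **Group structure.** A configurable fraction of antigens (default
  10%) gains a fixed depth shift (default 30) in group-1 sera.
- **Array effects.** Each serum's depths are scaled by a log-normal
  factor (default sd 0.15 on the log scale), creating exactly the
  inter-array effect quantile normalization must remove.
- **Scan rendering.** Spots are hard dark discs (radius 3 px in a
  12-px pitch by default) at both duplicate positions on a bright
  membrane (background 200) with optional linear gradient, Gaussian
  pixel noise (default sd 5), a small global rotation (bilinear,
  re-quantized to integers), and clipping to 0--255. Depths exceeding
  the background clip to black with a warning.

Not emulated: scanner point-spread, spot-morphology variation (comets,
doughnuts), expression-level variability, or serum chemistry. Passing
recovery tests therefore shows the pipeline is correct *given* roughly
disc-shaped spots on a locally smooth background; it does not certify
performance on degraded real membranes.

Default geometry (8 x 12 subgrids of 40 spots) accommodates 1827
antigens in duplicate, the panel size of the motivating assay; none of
the pixel geometry is claimed to match any particular scanner, and all
of it is configurable. The test suite exercises smaller arrays (tens to
hundreds of antigens, 2x3 to 5x5 subgrids) and panels of 500 antigens
with 80 to 127 sera -- sizes chosen so the full suite and the
permutation analyses stay comfortably fast while leaving every
statistical property measurable.

## Numerical choices and degenerate inputs

- Rounding of duplicate means is half-up (`floor(x + 0.5)`), clamped to
  0--255, because profiles are defined as 8-bit integers.
- 2-means splits between tied pixel values are excluded (the partition
  must be a threshold partition); the darker cluster is foreground.
- Empty foregrounds score 0 and are flagged, never dropped silently.
- Metrics with zero denominators (e.g. sensitivity without positives)
  are `NA`, not 0.
- `antigen_auc` on empty groups, single-class classification tasks, and
  layouts that do not fit their image are errors; a single-serum matrix
  passes through normalization unchanged with a warning; fewer sera
  than folds reduces the fold count with a warning.
- All randomness (simulation, fold draws, permutations) flows from
  explicit integer seeds; derived child seeds stay below 2^31.

## Limitations

- The quantification stage assumes the grid layout is known (as it is
  for arrays spotted by a gridding robot); it does not auto-detect
  subgrid positions from the image.
- The AUC informativeness rule inherits quantile normalization's
  compositional sensitivity discussed above.
- Confidence intervals are percentile intervals over 10 repetition
  medians; they describe the stability of the cross-validation
  estimate, not population-level uncertainty.
- Binary tasks only; multi-group designs are handled as a set of
  pairwise tasks by the caller.
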