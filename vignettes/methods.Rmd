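---
title: "Anomaly detection on L2-constrained deep features: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anomaly detection on L2-constrained deep features: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deeplof)
```

## The model

`deeplof` treats a rare, heterogeneous image class as *anomalous* rather
than as the second category of a binary classifier. The method has two
stages.

**Stage 1 — feature learning.** Each case contributes two registered
grayscale images (T1 and T2 roles). They are fused into one pseudo-color
RGB input: blue = T1, green = T2, red identically zero. A CNN is trained
as a three-class softmax classifier — normal (0), abnormal (1), auxiliary
texture (2) — where the texture class is a library of non-medical
procedural textures that forces the convolutional features to stay
general instead of overfitting the small cohort. The loss is the
L2-constrained softmax: the penultimate activation $f(x)$ is replaced by
$\alpha f(x) / \lVert f(x)\rVert_2$ before the classifier, so all feature
descriptors live on the sphere of radius $\alpha$ and cross-entropy
minimisation becomes cosine-similarity separation. Descriptors of the
compact normal class end up dense on the sphere; descriptors of the
diverse abnormal class end up sparse and far from the normal cluster.

**Stage 2 — anomaly scoring.** The Local Outlier Factor compares a query's
local density to the densities of its $k$-distance neighbors among the
*normal-class training descriptors*. Two density variants are
implemented. The `raw` variant uses the mean raw distance,
$\mathrm{lrd}(p) = \left(\sum_{q \in N_k(p)} d(p,q) / |N_k(p)|\right)^{-1}$;
the `reachability` variant substitutes the canonical reachability distance
$\max(k\text{-dist}(q), d(p,q))$, which is what standard library
implementations compute and is therefore the experiment default. Both are
oracle-tested against independent brute-force implementations. A case is
called abnormal when its LOF exceeds a threshold, by default the
Youden-index threshold of the test ROC (the report carries
`threshold_source = "test_youden"` so users can see that this operating
point is optimistically chosen on test data; a validation-derived
threshold can be substituted by thresholding scores from
`classify_scores()` directly).

### LOF conventions

* **Neighborhood ties.** $N_k(p)$ contains every reference within the
  $k$-th smallest distance, so $|N_k(p)| \ge k$ under ties. Distances are
  accumulated per dimension (not via the expanded square) so that exact
  ties — common on lattices and rounded data — are detected bitwise.
* **Leave-one-out.** A query identical to one stored reference drops that
  single reference; each neighbor's density is likewise computed against
  the references minus that neighbor. Scoring a training point therefore
  gives a finite, meaningful LOF.
* **Degenerate density.** If all neighbors of a query sit at distance 0
  its density is infinite; such a duplicate of a dense spot is not an
  outlier and its LOF is defined as 1.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 80 | radius of the feature sphere (unitless); 0 disables via `alpha = NULL` |
| `k` | 5 | LOF neighborhood size |
| LOF metric | squared Euclidean | distance used for densities |
| `learning_rate` | 1e-5 | Adam step size for the transfer-learning backbone |
| `batch_size` | 1 | gradient updates per image |
| `max_epochs` | 500 | training ceiling |
| `early_stop_patience` | 20 | epochs without validation improvement before stopping |
| `frozen_layers` | 10 (VGG16) / 0 (tiny) | weight-bearing layers, counted from the input, left untrained |
| `input_size` | 100 | network input side (pixels) |
| fractions | 0.6/0.2/0.2 | stratified train/val/test split |

Early stopping needs a patience definition: a literal "stop at the first
non-improvement" is noise-dominated at batch size 1, so the default waits
20 epochs and restores the best-validation weights; patience 0 remains
available and is covered by a test. "Freezing 10 layers" is interpreted as
the first 10 *weight-bearing* layers counted from the input (pooling
layers own no parameters); for VGG16 that freezes conv1_1 through conv4_3.

The augmentation stack runs every epoch: horizontal/vertical flips
(p = 0.5 each), rotation uniform in ±180° (bilinear, zero-filled corners —
tumor crops have dark backgrounds), random erasing (p = 0.5, area 2–33%,
aspect 0.3–3.3, the cited technique's conventional defaults), and mixup
with Beta(0.2, 0.2) weights. Mixup partners are drawn from the whole
epoch stream including texture images, since all three classes are trained
jointly; `mixup_scope = "cohort_only"` restricts pairing and passes
textures through unmixed. Soft labels stay on the simplex through the
whole stack and the loss consumes them as weighted cross-entropy.

## The synthetic cohort generator

The clinical cohort the method targets is private, so the generator
emulates its statistical structure rather than its pixels: 190 normal and
55 abnormal cases (22.4% prevalence) and 61 auxiliary textures. Normal
cases are drawn from 3 shared archetypes — smooth elliptical blobs with a
mild oriented texture — plus per-case Gaussian noise (sd 0.05) and a small
intensity jitter: a numerous, compact class. Abnormal cases come from 20
archetype families and additionally randomise their geometry per case
(center, radii, 2–8 boundary lobes, texture frequency and contrast): a
rare, heterogeneous class. The second image of each pair is a gamma
contrast remap of the same underlying field with independent noise,
emulating the T1/T2 contrast difference. Textures are full-field gratings,
plaids, checkerboards and smoothed noise.

What this emulates — class imbalance, compact-vs-diverse geometry,
correlated dual-contrast pairs — is exactly what the two-stage method
exploits. What it does not emulate: MR physics, partial-volume and coil
inhomogeneity effects, 3-D context, the radiological meaning of margins
and invasiveness, or inter-scanner variation. Passing tests on this
generator therefore demonstrate that the pipeline's machinery behaves as
specified and that the anomaly formulation beats a conventional classifier
*under the assumed structure*; they say nothing about clinical accuracy.

## The ablation benchmark

`default_benchmark_config()` mirrors the ablation ladder at desk scale:
the full 190/55/61 design rendered at 32×32 pixels, the `tiny_cnn`
backbone (three conv/ReLU/maxpool blocks, global average pooling, a dense
feature layer, the L2 constraint, a 3-way classifier) trained from scratch
with Adam 1e-3 for at most 25 epochs (patience 8), 5 seeds, two arms:
`conventional` (2-class softmax, no textures, no constraint) and
`texture_l2_lof`. Metrics are aggregated across seeds by the median. Two
scale choices depart deliberately from the reference recipe: the 1e-5
learning rate is a *transfer-learning* rate for a pretrained VGG16 and
cannot train a randomly initialised small CNN within tens of epochs, so
the from-scratch benchmark uses 1e-3; and 32×32 inputs with a ~7k-parameter
backbone keep the five-seed benchmark to minutes on one CPU. The softmax
arms map 3-class output to a binary score as $p_1 / (p_0 + p_1)$, since a
3-class posterior has no canonical binary reduction.

On this benchmark the synthetic classes are cleanly structured and both
arms typically reach high ROC-AUC; the benchmark's assertion is the
*ordering* (the LOF arm is at least as good as the conventional arm, both
above chance), not a reproduction of any particular cohort's numbers.

## Evaluation choices

* ROC-AUC is the Mann–Whitney pair-counting statistic (ties count half);
  the trapezoidal integral of the ROC curve agrees and is tested.
* PR-AUC is step-wise average precision, not trapezoidal PR
  interpolation, which is known to be optimistic.
* The Youden threshold maximises $J$ over midpoints of adjacent distinct
  scores plus infinite sentinels, with decisions by strict `>`; among
  equal-$J$ thresholds the most sensitive one wins (the screening-oriented
  tie-break).
* The DeLong variance comes from the structural components
  $V_{10}, V_{01}$ with sample variances and a normal-approximation CI
  clipped to [0, 1]; it is tested to 1e-12 against a loop-based oracle and
  cross-checked against pROC.
* Bootstrap CIs resample cases with replacement *stratified by class*
  (2000 replicates by default; the experiment driver uses fewer at mini
  scale), percentile 2.5/97.5.

## Numerical and degenerate-input conventions

* `l2_constrain()` refuses the zero vector (its direction is undefined);
  the network's constraint layer instead uses a 1e-12 norm guard so a
  transiently dead ReLU cannot crash training.
* Image resampling is bilinear (EBImage); resizing to the current size is
  exact identity, constants are preserved, and values are clipped back to
  [0, 1] after interpolation.
* `center_crop()` uses floor offsets and never interpolates.
* Split rounding is largest-remainder per class; published composition
  tables whose rounding differs are reproduced via `explicit_counts`
  (the 151/48/46 reference split is not the exact 60/20/20 rounding of
  245, which would give 147/49/49).
* All randomness flows through derived 32-bit seeds; cohorts, splits,
  augmentation streams, training and bootstraps are bitwise reproducible
  given a seed.

## Open choices resolved here

* Per-image intensity normalisation before fusion is unspecified in the
  reference protocol; images are used as-is in [0, 1] (no channel-mean
  subtraction). This keeps the pseudo-color contract bit-exact.
* Whether texture descriptors join the LOF reference set is unspecified;
  the default excludes them (`include_textures = FALSE`), since the
  reference set models the *normal tissue* density.
* The LOF reference scope defaults to normal-only training descriptors
  (novelty-detection reading); `fit_scope = "all_cohort"` is available.
* The number of texture images per epoch defaults to 61, one per material
  of the texture database the auxiliary class stands in for; it is
  configurable.

## Known limitations

The network engine is plain R: adequate for the tiny backbone and the
benchmark sizes, but training the full VGG16 topology at 100×100 is slow
and its pretrained weights must be supplied locally (`weights_path`) — no
download is attempted. The generator's simplifications listed above mean
benchmark metrics should never be quoted as clinical performance. DeLong
machinery covers a single AUC's CI; comparing two correlated AUCs is out
of scope. One-class SVM and autoencoder baselines are deliberately not
implemented.
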