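---
title: "Mapping sex differences in brain MRI with a 3D CNN and gradient saliency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping sex differences in brain MRI with a 3D CNN and gradient saliency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Biological sex can be classified from a T1-weighted brain MRI with high
accuracy, but the dominant confound is total intracranial volume (TIV):
female TIV is on average 10–15% smaller than male TIV.  A classifier trained
without TIV adjustment may simply be a brain-size detector.  `brainsexmap`
implements a complete, desk-scale version of the analysis that (1) trains a
3D convolutional sex classifier on minimally preprocessed volumes, (2)
derives voxelwise gradient class-saliency maps and aggregates them into a
composite *sex differences map*, (3) scores atlas regions by a weighted
saliency statistic, and (4) audits the classifier's reliance on TIV
post hoc, through tertile-stratified performance and the kernel-density
overlap interval of the two sexes' TIV distributions.

Because the multi-site MRI cohorts that motivated this design are
access-controlled, the package ships a synthetic phantom generator whose
cohorts have the statistical structure the analysis assumes.  Every stage is
exercised end-to-end on phantoms; nothing in the pipeline is specific to
phantoms, and NIfTI volumes from any source can be substituted.

## The classifier

The model is an SFCN-style fully convolutional network: five blocks of
3×3×3 convolution (padding 1) → batch normalization → 2×2×2 max pooling
(stride 2) → ReLU; a sixth block of 1×1×1 convolution → batch norm → ReLU; a
seventh block of average pooling over the remaining spatial extent, dropout
(p = 0.5, training only) and a final 1×1×1 convolution to a single
pre-sigmoid score.  Male is the positive class.  The average-pool kernel is
derived from the input shape as the extent remaining after five stride-2
floor-halvings — 6×7×6 for a full-scale 193×229×193 volume, 1×1×1 for the
48³ desk-scale grid:

```{r}
library(brainsexmap)
build_sfcn(c(193, 229, 193))$avgpool_kernel   # 6 7 6
```

Training follows the reference protocol: Adam, binary cross-entropy on the
sigmoid output, batch size 16, initial learning rate 0.01, reduce-on-plateau
(factor 0.1 after five epochs without validation-loss improvement), up to 50
epochs, on-the-fly augmentation rotating half the scans by up to 15°, and
selection of the epoch with the lowest validation loss.  The entire
forward/backward machinery (convolutions, pooling, batch norm, Adam,
back-propagated input gradients) is implemented in the package (R with
Rcpp/Armadillo kernels), which keeps the saliency computation exact with
respect to the model actually trained.

Channel widths are configurable.  The `build_sfcn()` default
(8, 16, 16, 32, 32, 16) is a compact configuration suitable for a single
CPU; the test-suite experiments use (4, 8, 8, 16, 16, 8) and 2–5 epochs so a
full multi-seed study fits in minutes.  `augment_rotate()` reads "rotated by
15°" as a rotation about one uniformly chosen axis by an angle uniform in
[−15°, 15°], drawn fresh at every epoch; the reference protocol does not fix
the axis or sign convention.

## Saliency and the sex differences map

For each correctly classified subject the class-saliency map is the absolute
gradient of the **pre-sigmoid** class score with respect to every input
voxel, computed in one backward pass with the network in evaluation mode.
The pre-sigmoid score is used because the sigmoid saturates for confident
predictions and would shrink gradients toward zero; with a single-logit
model the choice of target class does not matter, since
|∂(−s)/∂x| = |∂s/∂x|.  Maps are min-max normalized to [0, 1] within the
brain mask, averaged per sex over correctly classified subjects, and
averaged into a composite map over a TIV-balanced, correctly classified
subset (see below).  The composite is re-normalized to [0, 1] after
averaging (exposed as `renormalize` in `average_maps()`) so figures and
region scoring share a scale.

Region scoring uses a labelled parcellation: for each region, the *saliency
score* is the proportion of its voxels with saliency strictly greater than
0.1; the per-region mean saliency is min-max normalized **across regions**;
and the *weighted saliency score* is their product.  Regions are ranked by
the weighted score.  The across-regions reading of the normalization is the
only one under which exactly one region attains norm-mean 1, which is what
makes the weighted score comparable between regions.

## TIV bias audit

TIV is estimated from the brain mask (voxel count × voxel volume / 1000,
ml).  The audit has two parts:

* **Tertiles** — test subjects are split into three near-equal groups by TIV
  rank; per-tertile per-sex recalls and balanced accuracy mirror the
  quantile tables of TIV-bias analyses.  A classifier leaning on TIV shows
  the characteristic asymmetry: near-perfect female recall (and poor male
  recall) in the lowest tertile, the reverse in the highest, and the
  smallest recall gap in the middle.
* **KDE overlap** — Gaussian kernel densities of female and male TIV are
  evaluated on a shared 512-point grid spanning the pooled range ± 3
  bandwidths, with Scott's-rule bandwidths (σ·n^(−1/5)) recorded in the
  output.  Each sex's support is where its density is at least 20% of its
  own maximum; the overlap interval R_tiv is the intersection of the convex
  hulls of the two supports.  The threshold is relative to each sex's own
  maximum, the reading consistent with "excluding the low-density tails" of
  each distribution; an absolute threshold would make the result depend on
  the measurement scale.  Convex hulls avoid fragmenting R_tiv when a KDE is
  multimodal (fragmented supports are reported via a message).  An empty
  intersection is a valid, explicit result, not an error.

The composite map is built from correctly classified subjects with TIV
inside R_tiv, down-sampled at random (seeded) so both sexes contribute
equally.

## The synthetic cohort generator

`phantom_config()`/`generate_cohort()` emulate the study population the
analysis assumes:

* **Demographics** — sex assigned at a configurable female fraction (default
  0.53, the pooled multi-site value); ages uniform over 18–95; site (scanner
  vendor) and field strength assigned independently of sex with marginals
  11/8/81% (GE/Philips/Siemens) and 21/79% (1.5 T/3 T).  The joint
  distribution of these covariates is not published, so independence is the
  neutral choice.
* **TIV** — per-sex normal, truncated at ±3 SD, with the female mean equal
  to the male mean × (1 − deficit); the default deficit 0.125 sits mid-range
  of the reported 10–15%.  On the default desk-scale grid (48³ voxels at
  3 mm) TIV is rescaled proportionally: male mean 800 ml, SD 60 ml.  The SD
  preserves the ~7.5% coefficient of variation of adult TIV; the mean is the
  largest round value for which a +3 SD male brain still fits inside the
  grid's ellipsoidal envelope (~999 ml).  The full-scale 193×229×193 grid at
  1 mm remains configurable.
* **Anatomy** — each phantom is a brain-extracted ellipsoid (axis
  proportions 0.82 : 0.95 : 0.80, roughly left-right : anterior-posterior :
  inferior-superior) scaled by bisection so the voxelized mask volume
  matches the sampled TIV within 2%; three concentric intensity bands stand
  in for white matter (0.9), grey matter (0.6) and a CSF rim (0.35), plus
  Gaussian noise (SD 0.1) inside the mask.  Background is exactly zero.
* **Regional effects** — a toy atlas of disjoint spherical regions is placed
  inside a conservative envelope contained in even the smallest brain.
  Subjects of the effect-carrying sex (default male) receive an additive
  intensity shift (default experiments use 0.2) inside the chosen regions,
  intersected with the brain mask.  An additive shift in whole labelled
  regions keeps the planted ground truth exactly recoverable by region
  scoring, which is the point of the phantom: shape effects would confound
  recovery with registration error.

The two sex signals — volumetric (TIV deficit) and regional (intensity
shift) — are independent knobs.  The reference analysis cannot say how much
of the real sex signal is volumetric, so the generator deliberately does not
fix a ratio; the test suite instead exercises the two pure conditions
(deficit only, effect only), where the expected behaviour of each audit
stage is unambiguous.

What the phantoms do **not** emulate: MRI physics (bias fields, vendor
intensity profiles), skull/scalp, gyral anatomy, registration error across
subjects (phantoms are generated in a common space, so template alignment is
rigid rather than nonlinear — the principal fidelity gap relative to a real
multi-site study), or any site/field effect on intensities.  Passing tests
therefore demonstrate that the pipeline recovers planted structure under its
own assumptions, not that the real-data findings replicate.

## Preprocessing choices

* Z-scoring uses the **population** SD over **in-mask** voxels, with
  background reset to zero.  Whether background voxels enter the statistics
  is unspecified in standard descriptions; in-mask statistics make the
  normalization independent of the field of view.
* Rigid (6-DOF) registration minimizes the mean squared intensity
  difference through a 3-level mean-pooled pyramid with Nelder–Mead search
  at each level (derivative-free, as is usual for intensity-based
  registration).  Mean squared error is appropriate because all volumes
  share a modality and intensity convention after z-scoring.  The contract,
  verified in the tests, is recovery of planted transforms within 0.5
  voxel / 1° and preservation of mask volume within 2% (the property that
  motivates rigid registration in the first place).
* Splitting is stratified by sex × site × field (age is reported by
  subgroup but never stratified on).  Counts use largest-remainder rounding
  per stratum, followed by a deterministic correction so the global totals
  equal the largest-remainder rounding of n × (0.8, 0.1, 0.1) — a pooled
  cohort of 2,110 splits into exactly 1,688/211/211.
* Decision threshold is 0.5 on the male probability; a probability of
  exactly 0.5 classifies as female so the rule is total (a sigmoid never
  ties in practice).
* Age bins for subgroup reporting are [<55), [55, 70), [≥70], with both
  thresholds in the upper bin.

## Numerical and degenerate-input conventions

* Constant volumes cannot be z-scored and constant in-mask saliency cannot
  be min-max normalized; both raise a degenerate-input error.
* Metrics requiring both classes (balanced accuracy, AUC) are `NA` when a
  class is absent — never silently 0.  A tertile missing one sex gets `NA`
  recalls and is flagged.
* If all regions share one mean saliency, the across-regions normalization
  is degenerate; norm-means are defined as 1 with a warning.
* Ranking ties in `top_k()` break by saliency score, then region id.
* All randomness flows from one integer seed; stage seeds are derived by
  hashing the stage name with the global seed, so stages can be re-run in
  isolation and a fixed seed reproduces byte-identical tables and maps.

## Desk-scale protocol in the test suite

The stochastic experiments in the test suite use 48³ phantoms with the
(4, 8, 8, 16, 16, 8) channel configuration and three fixed seeds per
condition: the planted-effect condition (n = 200, no TIV deficit, two effect
regions at +0.2; 10 epochs, augmentation off) verifies that the composite
map concentrates saliency in the planted regions and that they rank at the
top of the weighted scores; the TIV-only condition (n = 600, deficit 0.125,
no regional effect; 10 epochs with the full augmentation protocol, a
50/25/25 split) verifies the tertile asymmetry, with the audit computed on
the pooled held-out validation+test subjects (300) so the extreme tertiles
carry stable per-sex counts and the larger validation set makes
lowest-validation-loss model selection reliable at desk scale.
Augmentation is disabled in the planted-effect runs because at 3 mm desk
resolution a ±15° trilinear rotation smears the 9-mm-radius planted spheres
and, with only tens of gradient steps, regularization has no overfitting to
counteract; in the TIV-only runs rotation is volume-preserving — it
multiplies the data for exactly the discriminative feature — and is kept
on.  At full scale (1 mm voxels, 50 epochs, thousands of scans) the
reference protocol applies unchanged and remains the package default.
These sizes are the package's chosen desk-scale study conditions; the same
code runs unchanged at full scale.

## Known limitations

* Gradient saliency is noisy at the single-subject level; the pipeline
  follows the reference design in averaging over correctly classified
  subjects rather than smoothing.
* The phantom's sex signals are idealized (see above); in particular there
  is no interaction between TIV and regional effects.
* Nonlinear template warping of native-space maps is out of scope; rigid
  alignment is exact for phantoms generated in a common space but would
  blur fine structure on real data.
* Training at the full 193×229×193 scale with the original SFCN widths is
  impractical on one CPU; the architecture supports it, but expect hours
  per epoch.
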