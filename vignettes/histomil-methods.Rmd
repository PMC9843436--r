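---
title: "Methods: desk-scale slide analysis with MIL calling and survival risk grouping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale slide analysis with MIL calling and survival risk grouping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model of the data

`histomil` implements, at desk scale, the full chain of a slide-level
histology analysis: foreground detection and patch tiling of whole-slide
images, pixel-level tissue segmentation, patch classifiers trained with
multiple-instance-learning (MIL) losses, slide-level mutation calling from
the *positive ratio* (the fraction of a slide's patches whose argmax
prediction is the mutation-positive class), tissue-microarray (TMA)
consensus rules, and a Cox proportional-hazards survival head whose
continuous hazard score in $[-1, 1]$ is partitioned into low /
intermediate / high risk groups by a constrained two-cutoff search.

Real clinical whole-slide images are access-restricted and GPU-scale; the
package therefore ships a first-class synthetic-slide generator whose
outputs carry the statistical structure the analysis assumes, so that
every downstream stage is tested end to end without any download.

# The synthetic-slide generator

## What it emulates

Each texture class is a stained background color field, plus
Poisson-scattered dark elliptical blobs standing in for nuclei, plus
oriented band-pass noise. Classes differ in blob density, blob radius,
and orientation coherence — exactly the locally computable statistics the
segmenter and classifiers consume. The default palette places a
near-white "glass" background (mean luminance ≈ 245) against darker
tissue classes, so Otsu thresholding separates foreground by
construction; `validate_textures()` enforces this, and enforces a
pairwise margin in at least one of the three local statistics between any
two tissue classes.

Slide-level genetics are emulated by *mixing*: a slide's `mutant_fraction`
is the share of its tumor pixels drawn from the `mutant_like` texture.
Mutant pixels are planted as spatially contiguous random disks rather
than i.i.d. pixels, mirroring subclonal regions; this is what makes the
patch-level positive ratio a meaningful slide statistic, and it produces
the dose–response between the planted fraction and the slide's positive
ratio that the mutation-calling tasks rely on. The mixing fraction plays
the role that the variant allele fraction plays in sequencing data.

TMA generation reuses the same textures: all cores of a patient share the
patient's class; each core is an independent realization (fresh noise and
blob placement), so duplicate-core agreement is a non-trivial statistic.
The canonical fixture uses 126 patients, duplicates for all but one
patient with four cores, i.e. 254 cores.

## Survival labels

Event times are exponential with rate
$\lambda_i = \lambda_0 \exp(\beta f_i)$, where the planted image risk
feature is the *centered* mutant fraction $f_i = 2\,\mathrm{mf}_i - 1 \in
[-1, 1]$ — the same scale as the model's hazard output. Censoring is
exponential and independent, with follow-up capped at
`max_followup_years`. The closed forms give direct checks: with
$\beta = 0$ and no censoring the mean event time is $1/\lambda_0$, and
the feature is independent of the outcome (verified by log-rank p-values
being uniform across seeds).

For the strong-effect survival study the generator defaults to a
near-clonal mixture (`mutant_fraction` uniform on $[0.7, 0.95]$ in half
the cohort, zero in the other half), so a coefficient of 1.5 produces a
log-hazard spread of about 3 between the two arms. With a weaker,
subclonal mixture the attainable concordance of *any* predictor is
substantially lower — bounded by the pairwise hazard ratios, not by model
quality — so the strong-effect condition is deliberately strong.

## What it does not emulate

No nuclear morphology, stain-deconvolution physics, pyramidal file
formats, scanner artifacts, or inter-site stain variation. Passing tests
demonstrate that the pipeline's logic and statistics are correct and that
the models recover planted structure from separable textures; they say
nothing about accuracy on real H&E images, which depends on
representation capacity deliberately out of scope here.

# Tiling and filters

Otsu's threshold is computed on the standard luminance combination
(0.299 R + 0.587 G + 0.114 B) by maximizing inter-class variance over all
256 cuts; ties (a plateau of equal variance) resolve to the plateau
midpoint, and the darker side is tissue. Patch extraction samples
top-left corners uniformly with rejection: patches with tissue fraction
below 0.5 are discarded, and, for the RAS-style task, patches with tumor
fraction below 0.66 as well. The attempt budget is 50 draws per requested
patch; exhaustion returns fewer patches with a warning flag rather than
an error. Coordinates are 0-based, half-open, in (row, col) order
everywhere. Higher magnification ("20x" from a 10x source) is simulated
by 2× nearest-neighbour resampling of the one base raster — no pyramid.
TMA cores are tiled on a regular overlapping grid; the stride defaults to
half the tile size and is configurable, since the original overlap is not
fixed by the protocol.

# Balancing and augmentation

The augmentation vocabulary is the dihedral group: rotations by 90°,
180°, 270°, the two axis flips, and the main-diagonal transpose (the
anti-diagonal variant is expressible by composition). Expansion is
materialized — originals first, then each op in recipe order — so the
patch-count arithmetic is exact: a 4-op recipe (original + rot90 + vflip
+ transpose) turns 4,000 base patches into 16,000; the 7-fold recipe
turns 5,200 into 36,400; the 5-fold recipe turns 4,000 into 20,000.
Oversampling takes each patch once and then draws the remainder with
replacement, which minimizes duplication while hitting the target count
exactly.

# Segmentation

## Model

At desk scale the segmenter is a multinomial logistic head over
hand-crafted per-pixel features: luminance and RGB, multi-scale box means
and standard deviations (integral-image filters), a center-surround blob
response, gradient energy, and structure-tensor orientation coherence.
These features span exactly the statistics the generator plants, so the
linear head is sufficient on high-margin palettes; the architecture is a
pluggable contract, and a deeper encoder could be substituted without
touching the loss, stitching, or metrics.

## Loss

Training minimizes weighted categorical cross-entropy plus a
Lovász-Softmax term:
$\mathcal{L} = \sum_c w_c \mathrm{CE}_c + \lambda \cdot \mathrm{LS}$.
The Lovász term is the sorted-gradient surrogate of the per-class Jaccard
loss, averaged over classes present in the batch; its gradient is
propagated through the softmax analytically. With $\lambda = 0$ the loss
reduces to weighted cross-entropy exactly. Probabilities are
epsilon-clamped before logs. Early termination keeps the
best-validation-loss checkpoint with a patience of 5 epochs (default), so
the returned model's validation loss never exceeds the initial one.

## Stitching and metrics

Whole-slide prediction averages per-pixel class probabilities over
overlapping patches before the argmax, which avoids seam artifacts; a
slide smaller than the patch is edge-padded and cropped back. Tissue
percentages are reported over non-background pixels. IoU metrics report
per-class intersection-over-union, the unweighted mean over classes
present in the truth, and a *weighted* IoU $\sum_c f_c\,\mathrm{IoU}_c$
with $f_c$ the truth pixel fraction — our reading of class-abundance
weighting; since the weights are a convex combination, weighted IoU
always lies between the worst and best per-class IoU, and exceeds the
mean exactly when abundant classes segment better.

# MIL classification and slide calls

Two batch-level MIL losses are provided, both motivated by the fact that
a slide-level label does not apply to every patch:

* **top-k** (default keep fraction 0.7, batch 144): per class, samples
  are ranked by their true-class score and the top
  $\lceil 0.7\,n_c \rceil$ contribute; cross-entropy is averaged within
  each class and then across classes. We read "top 70% of each class" as
  per class per batch; with identical scores, or keep fraction 1 on a
  balanced batch, the loss is plain cross-entropy.
* **mean/SD skip** (default multiplier 1.0): samples whose true-class
  score falls below mean − SD of the batch's true-class scores are
  skipped. The constant and direction are not fixed by the protocol; one
  SD below the mean is the package's choice, and an empty kept set falls
  back to the full batch with a warning.

Slide aggregation uses argmax counts, not probability sums: the positive
ratio is `n_positive / n_patches`, and a slide is called positive when
its ratio is greater than or equal to the threshold (the boundary is
inclusive by documented convention). Canonical thresholds are 0.2
(TP53-style), 0.1 (RAS-style), and a validation-derived threshold for the
MYOD1-style task, chosen to maximize the geometric mean
$\sqrt{\text{sensitivity} \times \text{specificity}}$ over midpoints of
sorted unique validation ratios (ties to the smallest candidate).

Model selection averages the probability outputs of the best `k` of `n`
trained networks by validation balanced accuracy, ties resolved toward
the lower fold index. TMA cores are called by simple patch-vote majority
(ties to the higher mean probability); patients are called by the
per-class geometric mean over their cores' probability vectors
(epsilon-floored), which reduces to the core call for single-core
patients and provably preserves a unanimous argmax.

# Survival branch

Subjects are partitioned into follow-up tertiles (264 cases give
88/88/88), each split 71/17 into training and validation, and batches are
balanced across the tertiles so no step is dominated by short or long
survivors. The head is linear over patch features; the subject score is
the mean head output over the subject's patches (the mean commutes with a
linear head), squashed by `tanh` to $[-1, 1]$. Training minimizes the
negative log Cox partial likelihood with Breslow tie handling,
$-\sum_{i: \delta_i = 1}\bigl[h_i - \log\sum_{j: t_j \ge t_i}
e^{h_j}\bigr]$, by seeded gradient descent with a small ridge penalty
(default 0.05) on the non-intercept weights. The ridge term matters for
the *null* behavior: with no signal, an unpenalized linear head overfits
batch noise and spreads hazards enough for the cutoff search to find
spuriously significant partitions; the penalty keeps a no-signal fit near
the constant-hazard solution, where the search correctly returns empty or
non-significant results. Fold ensembling averages the available per-fold
hazards per subject and clips to $[-1, 1]$.

Administrative censoring converts any record beyond the 12-year horizon
(default) into a censoring at the horizon, including events reported
after it.

## Cutoff search

The grid is indexed by integers to avoid floating drift: $C_L \in
[-0.9, 0.5)$ in steps of 0.05 (28 values), and for each $C_L$, $C_H \in
(C_L, 0.95]$ — 658 pairs in total. Groups are assigned by $h \le C_L$
(low), $h \le C_H$ (intermediate), else high. A pair passes when both
pairwise log-rank p-values (low vs intermediate, intermediate vs high)
are below 0.2 and every group holds between 10% and 50% of subjects;
among passing pairs the lowest three-group log-rank p wins, ties to the
smallest $C_L$ then $C_H$. Every evaluated pair is recorded in a ledger
with its pass/fail reason; an empty result is a first-class outcome. Only
the four listed constraints are implemented; the search result is
invariant to subject ordering by construction.

Log-rank tests and Kaplan–Meier curves are delegated to the `survival`
package (the de facto reference implementation) behind the module's
interface, and are verified against hand-computed fixtures in the tests;
with no events anywhere the statistic is defined as 0 with p = 1.

# Numerical choices and degenerate inputs

* Otsu on a constant image: threshold undefined; all-background mask
  with a warning.
* Zero probabilities: epsilon-clamped at 1e-12 before logs (CE, MIL
  losses, geometric-mean consensus), with a message.
* Ties: Otsu plateau midpoint; ensemble selection by lower fold index;
  TMA votes by higher mean probability; cutoff pairs by smallest
  $C_L$, $C_H$; geometric-mean threshold by smallest candidate.
* All randomness flows from one integer seed per entry point through an
  internal scoped-seed helper; the caller's RNG state is saved and
  restored, and every generator and trainer is a pure function of its
  arguments (verified by digest-identity tests).

# Problem sizes used in the shipped studies

The test suite and the acceptance script run entirely on CPU with
deliberately small problem sizes, chosen so each study finishes in
seconds to a couple of minutes while leaving clear statistical margins:
48–96 px slides, 16–32 px patches, 20–30 slides for the classification
studies, a 120-slide training cohort with an independent 200-slide test
cohort for the survival study, and 90-subject planted three-group cohorts
(10 seeds) for the cutoff-search recovery study. Sizes are parameters,
not constants; larger cohorts only tighten the same checks.

# Known limitations

* The linear heads cannot represent texture classes that match in all
  planted local statistics; the margin validator makes this explicit.
* The weighted-IoU definition (truth-fraction weights) is one plausible
  reading of class-abundance weighting.
* Whether the multivariate test should be a trend test across ordered
  risk groups is left open; the standard k-sample log-rank is used.
* Synthetic slides are stationary within a region; there is no
  within-class gradient structure, so segmentation boundary behavior is
  easier than on real tissue interfaces.
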