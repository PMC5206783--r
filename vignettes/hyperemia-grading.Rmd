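---
title: "Automatic grading of bulbar conjunctival hyperemia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic grading of bulbar conjunctival hyperemia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bulbar hyperemia — visible engorgement of the conjunctival vessels, "red
eye" — is graded in the clinic by comparing the patient's eye against a
photographic chart (the Efron scale, 0 = white eye to 4 = severe, scored
with decimal precision). The comparison is subjective and poorly
repeatable. `redeye` implements an objective replacement with three
stages:

1. **Segmentation** of the conjunctiva: six colour-threshold rules, each
   thresholding one colour plane at its arithmetic mean, combined by a
   per-pixel vote; a pixel is conjunctiva if at least $t_n$ of the six
   masks agree.
2. **Feature extraction**: the region of interest is decomposed into the
   whole conjunctiva (*o*), a central 512 px square (*t*) and a 1×2,
   2×1 or 2×2 grid of cells; 24 colour- and vessel-based features are
   computed in each region, giving $(mn + 2)\cdot 24$ values per grid.
3. **Regression** onto the grading scale: per-fold feature selection
   (CFS, RReliefF, or linear-SVR weights) followed by MLP, PLS or
   random-forest regression, scored by 10-fold cross-validated MSE.

Because clinical image sets with paired expert grades are rarely
shareable, the package also ships a synthetic scene generator that
reproduces the *structure* of such a study — graded scenes with ground
truth masks and two noisy simulated experts — so every stage is testable
offline.

## Colour conventions

All planes live on a common 0–255 scale, chosen so the red-hue constant
128 and yellow constant 240 used by the features are meaningful on the
hue wheel:

* **HSV**: hue rescaled from $[0°, 360°)$ to $[0, 255]$; achromatic
  pixels have $H = 0$ by convention.
* **TSL**: $S = \sqrt{\tfrac{9}{5}(r'^2 + g'^2)}$ with
  $r' = R/(R{+}G{+}B) - \tfrac13$, which is exactly 1 at pure red;
  black pixels (division by zero) are defined as $S = T = 0$.
* **L\*a\*b\***: sRGB primaries, D65 white, stored as
  $L \cdot 255/100$, $a^* + 128$, $b^* + 128$, so the neutral axis sits
  at exactly 128 and sums over $a$, $b$, $L$ are positive and
  commensurate with RGB sums. The linearisation uses an exact 256-entry
  lookup for 8-bit inputs, and the reference white is taken as the row
  sums of the sRGB→XYZ matrix so achromatic pixels are *exactly*
  neutral; agreement with `grDevices::convertColor` is within half a
  unit on this scale (the two derive the matrix slightly differently).

## Segmentation

The six rules and their polarities follow sclera optics: the sclera is
bright in green ($T_G$, and $T_{G'}$ which takes its threshold from the
central horizontal stripe, implemented as the middle third of rows),
bright in HSV value ($T_V$), desaturated in TSL saturation ($T_S$), and
low on the green–red opponent axis ($T_a$). $T_{S'}$ first suppresses
red ($R \leftarrow \min(R, G)$) so engorged vessels in severe cases do
not drag the saturation statistics; the suppression rule is one concrete
reading of "correcting the level of red" and is pluggable. The
threshold statistic is deliberately the plain arithmetic mean — not Otsu
— and each method's polarity flag is overridable.

Watershed and split-and-merge are included as *scored baselines only*;
they never join the vote. The watershed baseline runs EBImage's
intensity watershed on the smoothed green plane and keeps the largest
basin brighter than the image mean. Split-and-merge does a quadtree
split on green-plane variance (split while variance > 100 and block
side > 8 px), merges adjacent leaves whose means differ by less than 20
(static leaf means over the adjacency graph), and keeps segments
brighter than the image mean. These parameter values are package
defaults, not claims about any published configuration.

Sensitivity, specificity, accuracy and precision are computed from
per-pixel confusion counts; a metric with an empty denominator is
reported as `NA`, never as a number.

## Features

Vessel edges come from a Canny detector run on the green plane (the
plane with the best vessel/sclera contrast in ocular imaging):
Gaussian smoothing with $\sigma = 1.4$, Sobel gradients, non-maximum
suppression, and hysteresis whose high threshold defaults to Otsu's
threshold on the gradient magnitude with low $= 0.5\,\cdot$ high — all
config-exposed, since clinical contrast varies. Within a region, the
edge pixels form $VE$ and the rest $\overline{VE}$.

Conventions applied uniformly across the 24 formulas:

* sums run over region pixels only; $nm$ is the region pixel count and
  $n_r$ the number of distinct image rows the region intersects (the
  only reading under which the vessel-count feature is computable per
  region);
* $R/(R{+}G{+}B)$ contributes 0 for black pixels; ratio features over
  $VE$ return 0 when $VE$ is empty;
* F3, F4 and F13 are **raw sums** with no $nm$ normaliser, exactly as
  printed in the feature catalogue; they scale with region size and are
  rescaled downstream by the min–max normaliser;
* $\mu_{ij}$ (F13) is the mean of $H$ over the 3×3 neighbourhood of
  $(i,j)$ clipped to the region.

The implementation reduces every formula to per-class sums gathered in
two passes over the region; a literal per-pixel double-loop reference
implementation lives in the test suite and the two are required to
agree to $10^{-9}$ relative tolerance on randomised fixtures — this
oracle equivalence is the package's central correctness property.

The central square is centred on the integer-rounded centroid of the
conjunctiva mask (robust to asymmetric polygons, and it keeps the
square inside fleshy conjunctiva; bounding-box and image-centre
alternatives were considered and rejected as less robust). Images whose
mask cannot hold the square raise a structured "too small" error and
are dropped from feature tables with a warning — the same discard rule
a clinical protocol applies. One geometric caveat: an even-sided square
centred on an integer-rounded centroid can mirror only up to a
one-pixel lateral shift, so lateral-flip equivariance of the *t* region
holds up to that shift (exactly, when the centroid is half-integer).

Lateral orientation is normalised by mirroring images whose pupil side
differs from the canonical side (left). "Flipping" is interpreted as a
left–right mirror because its stated purpose is lateral pupil
alignment; pupil side is metadata (CSV column), not detected.

## Dataset preparation and regression protocol

Two graders score each image; records where they differ by **0.5 points
or more** are discarded (strict inequality), and the mean of the two
scores on the kept images is the ground truth. The grading table helper
also reports the grader correlation at several thresholds.

The cross-validation protocol is leakage-free by construction: within
each of the 10 seeded folds, the min–max normaliser and the feature
selector are fitted on the training rows only (the selector itself
aggregates over internal folds: features kept in ≥ 7/10 folds for CFS
and SVR weights, mean rank ≤ 10 for RReliefF). Normalisation is
per-fold rather than global — the original protocol does not say which,
and per-fold is the safe choice. If a fold's selection comes back
empty, that fold falls back to a grand-mean predictor.

Model families and the open choices behind them:

* **MLP** — `nnet`, one logistic hidden layer, linear output, plus
  skip-layer (direct input–output) connections so the network is at
  least as expressive as a linear model — appropriate here because the
  feature–grade relation has a strong linear backbone. The classic
  "(inputs+1)/2" sizing rule is capped at 8 units because `nnet`
  trains with full-batch BFGS whose per-iteration cost grows
  quadratically in the weight count; at 144 features the uncapped rule
  (73 units, ~10k weights) is computationally unusable. Early stopping
  — the intended regulariser — is implemented around `nnet` by
  training in short warm-restarted bursts (25 iterations each, at most
  20) and keeping the weights with the best error on a held-out fifth
  of the training rows; with feature count exceeding sample count the
  alternative (decay-only training to convergence) overfits badly.
  Predictions average 3 seeded restarts to tame initialisation
  variance; weight decay 0.1 is kept as a mild additional penalty.
  All of it is config-exposed (`size`, `decay`, `skip`, `restarts`,
  `chunk`, `max_chunks`, `patience`, `val_frac`).
* **PLS** — univariate NIPALS (mean-centred, unscaled),
  $\max(1, \min(10, p, n-2))$ components. The deflation loop stops
  early when the remaining covariance underflows, so constant targets,
  duplicated features and single-feature subsets (which the SVR-weight
  selector legitimately produces) degrade gracefully instead of
  failing. The implementation is cross-checked in the tests against an
  independent PLS implementation on well-conditioned data.
* **RF** — `randomForest`, 100 trees, seeded.

Predictions are clipped to $[0, 4]$. Two scoring references are worth
distinguishing when validating on synthetic data: the MSE against the
grader-mean ground truth — the only score available on real data —
carries an irreducible label-noise floor of $\sigma^2/2 \approx 0.06$
at the default grader noise (and the agreement filter cannot remove
same-direction grader errors), while the MSE of the same out-of-fold
predictions against the latent *true* grades isolates the feature
signal. `cross_validate_mse()` therefore returns its out-of-fold
predictions so both can be computed; the packaged validation asserts
the human-disagreement benchmark (0.25) on the former and the
parameter-recovery target (0.1) on the latter.

The experiment matrix runs every
(grid, selector, regressor) cell under one master seed, shares per-fold
selections across regressors (they do not depend on the regressor), and
writes CSVs shaped for side-by-side comparison — rows = grids, columns
= selectors, one file per regressor — plus a selected-features report.
A `cells_only` column scope drops the *o* and *t* blocks to ask whether
grid cells alone carry enough signal.

## The synthetic scene generator

A scene emulates what a slit-lamp photograph contributes to grading:

* near-white sclera (base RGB (238, 232, 226), jittered per scene) under
  a multiplicative illumination ramp of ±15 % in a random direction;
* curvilinear vessels: seeded random walks (step 1.5 px, angular noise
  0.25 rad — an L-system would add realism but not testing power)
  dilated to 3 px, with count $= 8\,(1 + \text{grade})$ and a diffuse
  redness shift proportional to grade/4 — so both vessel density and
  overall redness grow with grade, the two cues the features measure;
* a dark iris disc on one lateral side (the pupil side), eyelid
  occluders above and below (ellipse opening), and Gaussian sensor
  noise (sd 4 intensity units).

Expert graders are simulated as the true grade plus independent
N(0, 0.35²) noise, clipped to $[0, 4]$ and rounded to one decimal. At
this noise level the agreement filter discards roughly a third of the
records and the filtered correlation exceeds the raw one — the
qualitative regime of real paired-grader data. (A raw correlation as
low as real studies report would need grader noise so large that the
grader-mean ground truth itself becomes the accuracy bottleneck; the
default favours the documented noise value over matching the raw
correlation, and the filter's qualitative effect is what the tests
assert.)

What the generator does **not** model: specular highlights, depth of
field, vessel branching hierarchies, pigmentation, camera colour
profiles. Passing tests on these scenes therefore demonstrate that the
pipeline's machinery is correct and that its statistical behaviour is
as designed under controlled conditions — not that any particular
clinical accuracy will be attained on real images.

Scene geometry (eye opening, iris, conjunctiva mask) is a deterministic
function of the parameters, so datasets store parameters and render
pixels lazily one scene at a time; polygon ROIs are the convex hull of
the conjunctiva mask.

## Problem sizes and numerical choices

Scene parameters default to the 1600×1200 px acquisition format. The
packaged validation suite (`default_suite()`) generates 1024×768 scenes
— the smallest frame that preserves the full 512-px central-square
geometry with default eyelid coverage — at these sizes: 50 scenes for
the segmentation target, 200 scenes for grade recovery, 20 scenes per
grade level for monotonicity, 24 scenes for protocol-determinism
checks. Polygon rasterisation uses even-odd scanline filling over pixel
centres (half-open tie rule, a measure-zero case for hand-drawn
annotations). All randomness flows from a single seed per entry point;
seeded RNG use is wrapped so library calls never perturb the caller's
RNG stream.

## Known limitations

* The original study's numeric tables are not reproducible here: they
  depend on a private clinical image set and two human graders. The
  package reproduces the *protocol* and validates it on synthetic
  conditions.
* The hue scale, Lab encoding, stripe height, Canny parameters and the
  exact red-suppression rule are unstated in the source methodology;
  the conventions above are the package's own, fixed choices, each
  exposed in configuration where a practitioner might want to differ.
* The SVR-weight "wrapper" is a weight-magnitude filter around a linear
  SVR, not a search over subsets; a forward wrapper would be slower and
  is out of scope.
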