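---
title: "Detecting hand use and hand role from egocentric video: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hand use and hand role from egocentric video: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After a stroke, the two hands are typically affected unequally. How often
the more-affected hand is used at home, and whether it acts as a
*manipulator* (moving an object, with the hand-object contact area changing
over time) or a *stabilizer* (holding an object statically, contact area
constant), are clinically meaningful markers of recovery that clinic-based
assessments do not capture. Head-mounted (egocentric) cameras record these
behaviours in context, but turning hours of home video into usable measures
requires automation.

`egohand` implements a feature-based pipeline for two binary, per-hand,
per-frame classifications from such video:

1. **Interaction detection** — is this hand manipulating an object for a
   functional purpose (as opposed to resting contact or no contact)?
2. **Hand-role classification** — on interaction frames of bimanual tasks,
   is the hand the manipulator or the stabilizer?

together with the evaluation protocol appropriate for subject-level
generalization (leave-one-subject-out cross-validation with macro and micro
averages, stratified by the more-/less-affected hand) and the inter-rater
agreement statistics used to qualify frame-level annotations (Cohen's
kappa and PABAK).

Hand detection and segmentation are *not* part of the package: bounding
boxes and segmentation masks are inputs, as produced upstream by detection
and segmentation networks. The package consumes them together with the
colour frames.

## The instance and its features

An *instance* is one hand in one frame; a frame with two visible hands
contributes two independent instances. The hand's bounding box splits the
frame into three regions: the **hand** (mask pixels inside the box), the
**non-hand** remainder of the box, and the **background** outside the box.
The intuition: during a hand-object interaction the non-hand part of the
box is dominated by the manipulated object, so the hand-vs-non-hand and
non-hand-vs-background contrasts carry the signal.

Per instance the feature vector concatenates:

* **Colour (144 values).** Per HSV channel, 16-bin L1-normalized
  histograms per region; for each of the three region pairs the signed
  bin-wise difference of the two histograms. Signed bin-wise subtraction
  (rather than a scalar histogram distance) preserves *which* bins differ,
  which is what a tree ensemble can exploit. Every entry lies in [-1, 1]
  and each 16-bin difference block sums to zero.
* **Motion (96 values).** Dense optical flow from the instance frame to
  the next; per region, 16-bin histograms of flow magnitude (clipped to
  [0, 8] px/frame) and direction ([0, 2&pi;)), differenced over the same
  three region pairs. Under pure camera motion all regions move together
  and the differences vanish; hand-specific motion survives the
  subtraction.
* **Shape (1764 values).** A histogram-of-oriented-gradients descriptor of
  the box crop: crop resized to 64x64 intensity, 8x8-pixel cells, 9
  unsigned orientation bins, 2x2-cell blocks with L2 normalization.
  Captures hand posture (open vs closed fist) independently of colour.
* **Size change (10 values, role variant only).** Consecutive differences
  of the hand-mask pixel count over the instance frame and the ten
  subsequent frames, normalized by the instance's box area. Finger
  movements during manipulation modulate the apparent hand size;
  stabilizers hold it constant. The window is causal (current frame
  forward); when the task ends or the hand leaves the frame the remaining
  entries are zero, equivalent to repeating the last available mask.

The interaction variant is therefore 2004 values, the role variant 2014.
A hand with no bounding box produces a distinguished *no-box marker*
instead of numbers: by rule it is classified as no interaction and no hand
role without consulting any model.

The histogram bin counts, flow clip, and HOG geometry are package
defaults chosen for stability at the synthetic desk scale; all are
configurable through `feature_config()` and recorded in a fingerprint that
travels with trained models, which refuse to predict mismatched features.

### Optical flow

No dense two-frame optical-flow estimator exists in the R ecosystem this
package can depend on, so a pyramidal Lucas-Kanade estimator is included:
intensity frames are decimated into a 3-level pyramid, and at each level a
windowed least-squares solution of the brightness-constancy equations
refines the upsampled coarser estimate after warping the second frame.
By default the estimate is computed on a 2x-decimated working image
(quartering cost) and upsampled to full per-pixel resolution. Identical
frames give exactly zero flow. The flow algorithm is a pluggable contract
(`flow_fn` in `feature_config()`): any function mapping two intensity
matrices to per-pixel `(u, v)` may be substituted, and the package's tests
rely only on qualitative properties (zero flow for identical frames,
near-uniform flow under global translation, correct dominant direction for
a moving textured patch) rather than on this particular estimator.

## Classification

Each target uses a binary random forest with **150 trees** (the `ranger`
implementation; its default depth, leaf-size and feature-subsampling
settings are accepted, and fits use a fixed seed and a single thread for
reproducibility). Class imbalance in the role task (manipulation is the
minority at roughly 20/80) is addressed by a **weighted loss**, realized
as a class weight of 20 on the manipulation class; sample-level
reweighting would be an equivalent alternative. Because bootstrap
resampling depends on row order, instances are sorted into a canonical
(participant, task, frame, hand) order before fitting, making the fit
invariant to how the caller assembled the rows.

Prediction produces a positive-class probability. Thresholding happens
only *after* aggregation:

* **Duplicate rule.** If a hand has several predictions in a frame (e.g.
  two detections of a right hand), the final prediction is their average;
  an average >= 0.5 — inclusive, so a tie is positive — is an interaction
  (or manipulation).
* **No-box rule.** A hand without a bounding box is no interaction and no
  role, with probability 0 recorded in the decision's provenance.
* **Window rule.** For models that classify overlapping multi-frame
  windows (32 frames for interaction, 16 for role, 50% overlap), each
  frame receives the predictions of the windows covering it — two for
  interior frames — and the final label is their logical OR. A remainder
  at the task end is covered by a final truncated window, flagged in the
  span table.

## Evaluation protocol

Leave-one-subject-out cross-validation: each fold holds out all home tasks
of one participant as the test set; the validation set takes one bimanual
home task from every other participant (the forest does not consume a
validation set, but the fold structure is shared so window-based model
variants can plug into the same protocol); everything else trains. Two
training conditions are compared: *home only*, and *both* (home plus the
cleaner laboratory-recorded supplement). No task of the held-out
participant ever appears in training or validation, and the driver asserts
this on every fold.

Per fold, final per-frame decisions are scored against ground truth as
confusion counts, stratified into more-affected / less-affected / overall
by each participant's affected side. Five metrics are reported: Matthews
correlation coefficient (MCC), F1, precision, recall, accuracy.

* **Macro average**: the metric per held-out participant, then mean and
  sample (n-1) standard deviation across participants — every participant
  counts equally. Participants contributing no instances to a stratum are
  excluded from that stratum's macro average.
* **Micro average**: confusion counts pooled over all participants, the
  formulas applied once — every frame counts equally. Micro averages pool
  frame-level final (post-fusion) decisions.

Any metric with an empty denominator is reported as 0; MCC is also 0 when
any factor of its denominator vanishes. These conventions matter in
strata that a fold leaves almost empty.

## Inter-rater agreement

Frame-level annotation of interactions is subjective enough that its
reliability must be quantified. For two raters' binary labels aligned on
(participant, task, frame, hand), the package reports observed agreement
p~o~, Cohen's kappa (chance-corrected via the raters' marginal
distributions, with the degenerate both-raters-constant case defined as 1
for perfect agreement and 0 otherwise), and PABAK = 2p~o~ - 1, which
corrects kappa's sensitivity to prevalence and rater bias and depends on
the table only through p~o~. Interpretation bands use inclusive lower
edges: 0.61-0.8 substantial, 0.81-1 almost perfect (lower bands: below 0
poor, then slight / fair / moderate in 0.2 steps). Only 2x2 agreement is
implemented, matching the binary labels; multi-rater and weighted variants
are out of scope.

## The synthetic cohort generator

The study data this pipeline targets — home recordings of stroke
survivors — cannot be shared, so the package ships a synthetic
egocentric-scene generator that serves as its test bed. It emulates the
*structure* of such a study:

* **Participants** with an affected side (fair coin), impairment severity
  (Beta(2, 2)), and a closed-hand probability rising linearly with
  severity (0.1 + 0.8 x severity) — reproducing the confound that closed
  fists are common at rest after stroke, on the more-affected side.
* **Tasks** of three kinds per participant: at least one all-negative task
  (hands present and moving, no object contact), at least one bimanual
  task (one hand manipulating in sub-spans — sliding along the object at
  ~1 px/frame with a pulsing aperture, so the contact area changes every
  frame — the other statically stabilizing), and unimanual tasks (the
  less-affected hand drags the object at constant speed; the idle hand may
  leave the frame for a scripted span, exercising the no-box rule).
* **Scenes**: smooth-noise textured background translated by a clipped
  random-walk camera offset, a gradient-textured object rectangle, and
  skin-toned hand ellipses (per-participant HSV jitter) flattened when
  closed; Gaussian sensor noise; 8-bit quantization. The `home`
  environment uses larger camera steps and noise than `homelab`.
  Ground truth — tight boxes, exact masks, per-frame labels — falls out of
  the geometry. Default frames are 320x180 (the 16:9 aspect of typical
  egocentric analysis resolutions at desk-scale cost).
* **Class priors**: the interaction episode length is solved from the
  targeted interaction fraction, defined over hand instances of
  non-negative tasks (with a whole negative task per participant, a
  fraction like 0.7 over *all* instances would be structurally
  unreachable; the convention is stated on `cohort_spec()` and realized
  fractions are recorded in the manifest). The manipulation fraction among
  bimanual interaction instances is targeted at 0.2 by sizing the
  manipulator's sub-spans; defaults are 0.7 / 0.2.

Coordinates are 0-based with origin top-left and half-open boxes
[x0, x1) x [y0, y1), everywhere.

What the generator deliberately does **not** emulate: photorealism, real
hand shapes and grasp diversity, other people's hands, illumination
changes, motion blur, or annotation noise. Passing tests on this cohort
demonstrate that the pipeline's machinery — features, fusion rules,
protocol, metrics — is correct and that the features carry the intended
signal when colour/motion contrast is strong; they do not demonstrate
real-video accuracy, which in the target application is far below the
synthetic ceiling.

## Numerical choices and degenerate inputs

* Histogram binning is half-open with the top edge folded into the last
  bin; empty regions yield zero histograms (not NaN), so no feature is
  ever NaN/Inf for valid inputs.
* The Lucas-Kanade normal equations are Tikhonov-regularized (1e-3 on the
  diagonal) and non-finite solutions are zeroed, so textureless windows
  give zero flow rather than noise.
* HOG blocks with vanishing norm are left at zero rather than divided by
  an epsilon.
* Ties: the duplicate-fusion threshold is inclusive (>= 0.5 positive);
  kappa interpretation bands are inclusive at their lower edge.
* Degenerate boxes (zero width/height, outside the frame) are validation
  errors; an empty hand mask is accepted and flagged, the caller decides.
* Macro SD over a single participant is NA, printed as missing rather
  than 0.

## Problem sizes

The shipped analyses and tests run at sizes chosen to make the full
pipeline — rendering, flow, forests, folds — exercisable on a laptop-class
single core: the analysis drivers use 6 participants x 4 tasks x 120
frames; the acceptance checks use the same cohort at 300-frame tasks for
the end-to-end signal and chance-control runs. Feature extraction
dominates at roughly 60 ms per frame; forest training is a few tens of
seconds per fold at ~10,000 training instances.

## Known limitations

* The synthetic cohort's strong colour/motion contrast makes interaction
  detection nearly saturate; it is a correctness harness, not a difficulty
  benchmark.
* The included flow estimator underestimates large displacements on
  fine-grained textures; the feature histograms only need relative
  contrasts between regions, which survive this bias.
* Duplicate detections never arise from the generator (one observation per
  hand per frame), so the duplicate-averaging rule is exercised by unit
  tests rather than end-to-end.
* Model-comparison inferential statistics (ANOVA/Friedman and post hoc
  tests across classifiers) are not re-implemented; they are standard
  calls (`stats::aov`, `stats::friedman.test`, ...) on the per-participant
  metric tables this package produces.
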