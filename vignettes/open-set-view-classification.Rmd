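---
title: "Open-set view classification and quality assessment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-set view classification and quality assessment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(openecho)
```

## The problem

Routine cardiac ultrasound exams consist of dozens of short cine loops,
each acquired from a standardized scan plane ("view"). Downstream
analysis needs two manual selection steps automated: identifying the
view of each video, and picking the acquisition with the best image
quality. A classifier trained only on curated, known views fails
silently on the open set it will meet in deployment — videos of poor,
unrecognizable quality, views from categories absent at training time,
and videos that drift between two views while the probe moves.
`openecho` implements a three-part method for this setting:

1. **View classification.** A 2-D convolutional network classifies each
   frame of a video independently, producing a logit vector
   $\hat{y}_t \in \mathbb{R}^C$ per frame. The video-level logits are the
   temporal mean $\bar{y} = \frac{1}{T}\sum_t \hat{y}_t$, and the
   predicted view is $\arg\max_c \bar{y}_c$.
2. **Unknown-view recognition.** The maximum video-level logit
   $S = \max_c \bar{y}_c$ is a familiarity score: DNN logits behave like
   weighted sums of learned features, so inputs lacking those features
   receive uniformly low activations. A video is accepted as a known
   view iff $S \ge \delta$, where $\delta$ is calibrated on a validation
   set containing both knowns and unknowns.
3. **Quality regression.** Per-frame penultimate activations are
   averaged over time into an embedding $\bar{\ell} \in \mathbb{R}^D$,
   and a sparse linear head maps $\bar{\ell}$ to a quality score in
   $[0,1]$, fitted by minimizing

   $$\mathrm{Loss} = \frac{1}{2N}\sum_{k=1}^N \lVert w\cdot\bar\ell_k + b - y^q_k\rVert^2 + \alpha\lVert w\rVert_1 ,$$

   with $\alpha$ chosen by five-fold cross-validation and predictions
   clamped to $[0,1]$. (Some write-ups of this objective place $b$
   inside the residual with the opposite sign; the two forms are
   algebraically identical up to the sign of $b$, and this package uses
   the standard residual $w\cdot\bar\ell + b - y^q$.)

The anomaly-score module also implements the standard alternatives for
comparison: maximum softmax probability, mean penultimate activation
(L1), negated feature entropy (natural log, $0\log 0 := 0$, the all-zero
vector mapped to the minimum $-\log D$ and flagged), the relative
frequency of the modal per-frame prediction, and — for outlier-exposed
models — the summed known-class softmax. All scores are sign-oriented so
that *rejection is always "score below threshold"*, and the acceptance
boundary is uniformly inclusive ($S \ge \delta$ accepts).

## Evaluation metrics

With $y$ the reference label, $\hat y$ the prediction, $\mathcal{C}$ the
known-class set and $S(X)$ the familiarity score:

* **Closed-set accuracy**: accuracy over known-view videos only.
* **Full-set accuracy** at $\delta$: (correctly classified *and*
  accepted knowns + rejected unknowns) / all videos.
* **TPR / FPR** for the accept decision: knowns accepted / knowns, and
  unknowns accepted / unknowns; **balanced accuracy** is their
  sensitivity/specificity mean.
* **OSCR**: the fraction of knowns that are correctly classified *and*
  accepted, plotted against FPR as $\delta$ sweeps; the area under that
  curve (trapezoidal, endpoints forced to FPR 0 and 1) summarizes joint
  open-set performance. OSCR $\le$ TPR pointwise by construction.
* **Known-view ROC-AUC**: one-vs-one (Hand–Till) — for every unordered
  class pair, the Mann–Whitney AUC of each class's score on the
  two-class subset, averaged within the pair and then unweighted across
  pairs. This keeps the metric independent of the class distribution.
  Per-class video logits are the default scores (a configuration switch
  allows softmax probabilities, which can rank differently within a
  pair).
* **Unknown-view ROC-AUC**: Mann–Whitney statistic of $S$ separating
  knowns from unknowns (ties count one half); reported overall and per
  unknown subcategory, where each subcategory's ROC removes the other
  two subcategories from the test set.
* **Spearman correlation** between predicted and reference quality.

Threshold-swept curves and the calibration search share one candidate
grid: midpoints between consecutive sorted unique scores plus
$\pm\infty$ sentinels. This grid exhausts every distinct accept/reject
partition, so the calibrated $\delta^*$ is exactly optimal for its
criterion; ties break toward the smallest candidate, which favors
acceptance (false acceptances over false rejections). Two calibration
criteria are provided: maximum full-set accuracy (the default; sensitive
to the prevalence of unknowns in the validation set) and the mean of
OSCR and unknown-view specificity (prevalence-invariant).

## The synthetic phantom generator

No clinical data ship with the package; a generator produces sector-fan
phantom videos that make every stage trainable and testable:

* **Geometry.** A fixed sector-fan mask (apex at top-center, 75°
  aperture, depth 0.88 of the frame) over a dark background; pixels
  outside the fan are exactly 0. Each view class is a deterministic
  layout of 2–4 bright-walled elliptical "chambers" whose interiors are
  darker than background. Layout families are constructed so distinct
  classes differ in chamber count or primary-chamber position by at
  least 0.1 of the frame — a separability guarantee, verified in tests
  by a pixel-space nearest-centroid classifier (> 90% accuracy on
  default-quality clips). Twelve layouts exist by default: ten
  assignable as known classes, two reserved for the novel-category
  unknowns.
* **Motion.** Chamber axes pulse and centers bob periodically over a
  16-frame cardiac cycle.
* **Speckle.** Multiplicative log-normal noise
  ($x \mapsto x\,e^{\sigma Z - \sigma^2/2}$, default $\sigma = 0.3$) —
  the standard first-order texture model for B-mode ultrasound, cheap to
  compute.
* **Quality.** Four degradation axes in $[0,1]$ (visibility / contrast,
  centering offset, gain deviation, depth mismatch) modeled after the
  components of questionnaire-based quality rating. The ground-truth
  quality is the fixed convex combination
  $0.4\,\mathrm{vis} + 0.2(1-\mathrm{cent}) + 0.2(1-\mathrm{gain}) +
  0.2(1-\mathrm{depth})$; any monotone combination would do for
  parameter-recovery testing, and fixing the weights keeps tests
  reproducible.
* **Unknown subcategories.** *Novel category*: a reserved layout never
  assigned to a known class, rendered at normal quality. *Poor
  quality*: a known layout with visibility forced below 0.1, making the
  structures unidentifiable. *Multiple views*: the layout switches
  between two different known classes at a frame index drawn uniformly
  from $[T/4, 3T/4]$.
* **Splits and determinism.** Every output is a pure function of
  (arguments, seed); split seeds are `master + fixed offset` so splits
  are reproducibly disjoint. The training split never contains unknowns
  unless an outlier-exposure dataset is explicitly requested, in which
  case unknown clips enter training under a single collapsed
  `"outlier"` label without fine-grained subcategory.

What the phantoms deliberately do **not** model: wave propagation or any
transducer physics, anatomical realism of actual cardiac views,
vendor-overlay artifacts, or inter-rater ambiguity in quality labels.
Passing tests on phantoms therefore demonstrate that the implementation
of the method is correct and that the pipeline can learn and reject as
designed — not that clinical-grade accuracy would transfer to real
echocardiograms.

## Preprocessing and augmentation

Raw frames (RGB in $[0,255]$ or grayscale) are converted to
single-channel $[0,1]$ by the *unweighted* channel mean — the choice
that corresponds to averaging a pretrained RGB input layer into one
channel — then optionally cropped by a configurable rectangle (the
generic stand-in for metadata-driven removal of vendor overlays),
resized to the target height with preserved aspect ratio (bilinear), and
center-cropped to a square. If the post-resize width falls short, the
frame is zero-padded symmetrically rather than stretched.

Training-time augmentation applies, in order and each with probability
0.5: rotation (uniform in ±25°), gamma correction (uniform in
$[0.5, 2]$), resized crop (scale uniform in $[0.2, 2]$), elastic
distortion (intensity 2 px), and additive Gaussian noise
($\sigma = 0.01$); outputs are clipped to $[0,1]$. Three documented
choices where the recipe leaves room: **all frames of a clip share one
parameter draw** (independent per-frame warps would destroy the temporal
consistency the video-level aggregation relies on); geometric fill is 0
(background black); interpolation is bilinear everywhere. The geometric
stages are composed into a single coordinate map so each frame is
resampled once. Frame sampling: training draws `n` frames uniformly
without replacement (with replacement only for clips shorter than `n`,
which real recordings essentially never are but short synthetic fixtures
can be), returned in temporal order; test time always uses the full
sequence.

## Classifier and training

Two backbones are configured. The full-scale reference is
ResNet-50-v2 — pre-activation bottlenecks with group normalisation and
weight standardisation in place of batch normalisation — which this
package can build and train but which is impractical without accelerated
hardware. The desk-scale default is a four-block CNN (strided 5×5 then
three strided 3×3 convolutions, channels 12/24/48/128, group
normalisation with 4 groups, ReLU, global average pooling, linear head),
giving a 128-dimensional embedding. Both process frames independently;
there is no temporal mixing before the logit/feature averaging.

Training follows AdamW with $\beta = (0, 0.999)$, $\varepsilon = 10^{-8}$
and decoupled weight decay 0.01 applied to weights (not to norm
scales/biases); mini-batches of 16 videos × 8 frames; class-balanced
sampling (class uniform, then clip uniform, with replacement); an epoch
defined as `ceil(N / batch_videos)` iterations; per-frame cross-entropy
against the clip's view label (the recipe specifies cross-entropy for a
frame-independent CNN; per-frame application is the direct reading and
is what the implementation uses). Full-scale defaults are 300 epochs at
learning rate $10^{-4}$ with tenfold drops after epochs 150 and 250. All
randomness funnels through one master seed; the per-epoch learning rate,
loss and frame accuracy are logged. No best-epoch selection is
performed: the final-epoch model is returned and the full log is kept,
since the selection rule is otherwise unspecified and validation-based
selection would entangle the calibration split with model choice.

## Numerical choices

* **Quality Lasso.** The solver is cyclic coordinate descent on the
  centred Gram reformulation (intercept unpenalised and separated out),
  with warm starts down a decreasing penalty path, active-set sweeps,
  and convergence when the largest coefficient update falls below
  `tol` (default `1e-8`; the path solver is exercised against
  closed-form soft-thresholding and an independent coordinate-descent
  implementation to `1e-6` objective tolerance in the tests). The
  default grid is 50 log-spaced penalties from the data-derived
  $\alpha_{\max}$ (smallest penalty zeroing all weights) down four
  decades; the selection rule is minimal mean out-of-fold MSE with a
  seeded fold partition (no one-standard-error rule). Features enter
  unstandardised, matching the loss exactly as written; a
  standardisation flag exists but defaults off.
* **Quality bins.** poor $[0, 0.25]$, fair $(0.25, 0.5]$, good
  $(0.5, 0.75]$, excellent $(0.75, 1]$ — every boundary belongs to the
  lower bin.
* **Degenerate inputs.** Calibration without unknowns under the
  full-set-accuracy criterion warns and returns the $-\infty$ sentinel
  (accept everything); constant quality labels return the
  intercept-only model with a warning; the all-zero embedding gets the
  minimum entropy score with a flag; Spearman on constant vectors and
  closed-set accuracy without knowns are errors.
* **Ties.** Argmax ties break toward the lowest class index; tied
  anomaly scores at $\delta$ are accepted ($\ge$); tied ROC scores count
  one half.

## Desk-scale benchmark conditions

The built-in benchmark (`run_open_set_benchmark()`,
`run_quality_benchmark()`) fixes the following problem sizes, chosen so
the whole pipeline trains from scratch in minutes on one CPU while
leaving every stage non-trivial: 10 known classes × 50 training clips,
validation 5 clips/class plus 30% unknowns, test 8 clips/class plus 45%
unknowns (split equally over the three subcategories), 16 frames per
clip rendered at 256×256 and preprocessed to 64×64 network inputs, the
small CNN trained 12 epochs at learning rate $10^{-3}$ with drops after
epochs 8 and 11, and the quality stage fitted on 50 wide-quality-range
clips per class with a 10-per-class held-out set. The rejection
threshold is calibrated on the validation split by maximum full-set
accuracy. With these conditions the synthetic task is solvable to
high accuracy — which is the point: failures then indicate
implementation defects, not data ambiguity.

## Known limitations

* Phantom realism is deliberately minimal (see above); reported
  benchmark numbers characterize the implementation on synthetic data
  only.
* The desk-scale CNN processes 64×64 inputs; fine-grained distinctions
  that depend on 224-px detail are out of reach of the default
  configuration (the preprocessing path supports 224 and the ResNet
  backbone is available behind configuration).
* The method does not differentiate *which* unknown subcategory caused a
  rejection at deployment time; subcategory labels exist only for
  evaluation.
* Quality scores are modeled as point estimates; rater uncertainty and
  soft labels are out of scope.
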