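---
title: "Methods: class-imbalance-aware training and evaluation for retinal fundus classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: class-imbalance-aware training and evaluation for retinal fundus classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fundusbalance)
```

## The problem

Screening models for the most prevalent retinal diseases — diabetic
retinopathy (DR), glaucoma (GL) and age-related macular degeneration
(AMD) — are best trained on corpora pooled from many public fundus-image
collections, because single-source datasets bake in the biases of one
camera, one clinic and one population. Pooling, however, produces severe
class imbalance: a merged corpus of this kind contains on the order of
86k normal, 34k DR, ~3.8k glaucoma and ~600 AMD images. A classifier
trained naively on such data buys overall accuracy by ignoring the
minority classes, which is exactly wrong for screening.

`fundusbalance` implements a threshold-based *two-stage* remedy together
with the standard resampling baselines, and the evaluation protocol to
compare them fairly:

1. **Threshold split** (`threshold_split()`): the cardinality *t* of a
   reference minority class (glaucoma by default) defines a threshold.
   All glaucoma and AMD images, plus a uniform random sample of *t*
   normal and *t* DR images, form the balanced **fine-tuning** subset;
   the excess normal and DR images form the binary **pre-training**
   subset. With the merged-corpus census above, this yields a fine-tuning
   set of 3,787/3,787/632/3,787 (11,993 images) and a pre-training set of
   82,628 normal + 30,592 DR. The split conserves every record and never
   routes glaucoma or AMD to pre-training.
2. **Two-stage training** (`pretrain()`, `finetune()`): a 2-output model
   (normal vs DR, cross-entropy weights 1:2) is trained on the excess
   subset; its classification head is then replaced by a randomly
   initialized 4-output head, half of the feature-extractor layer groups
   are (re-)frozen, and the model is fine-tuned on the balanced subset
   with class weights 1, 0.9, 1.5, 1.2 for normal, glaucoma, AMD, DR.
3. **Baselines** (`ros()`, `rus()`): random minority oversampling with
   replacement up to the maximum class count, and random majority
   undersampling without replacement down to the minimum, applied to
   training folds only.
4. **Evaluation** (`make_folds()`, `run_cv()`, `compare_methods()`):
   stratified k-fold cross-validation with rotating validation/test
   folds. Validation and test folds are *thresholded* — normal and DR
   capped at the fold's glaucoma count — so all arms are scored on
   identical, fine-tuning-ratio evaluation data. Per class we report
   one-vs-rest accuracy, F1, sensitivity, specificity and AUC (percent),
   macro averages, overall accuracy, and mean ± standard deviation across
   folds with ROC bands.

## Training recipe and its parameters

Both training stages share one recipe: rectified-Adam, batch size 32,
weight decay 1e-5, a per-epoch cosine-annealed learning rate
η(t) = η_min + ½(η_max − η_min)(1 + cos(πt/T_max)) with T_max = 20, and
early stopping on validation loss with patience 5, restoring the
best-epoch weights. `train_config()` defaults encode this recipe with
η_max = 3e-4 and η_min = 1e-5 — the setting appropriate for fine-tuning a
large ImageNet-pretrained backbone.

The weighted cross-entropy loss is `-w[y] log p[y]` per sample with the
batch reduced by the *sum of the samples' weights* (weighted mean). This
is the dominant framework convention; it matters because it changes the
loss scale, so it is stated explicitly and covered by unit tests.

"Freezing half of the layers" is interpreted as the first
`ceiling(freeze_fraction * L)` of the L feature-extractor layer groups by
depth (not by parameter count); for the 4-block tiny CNN with
`freeze_fraction = 0.5` blocks 1–2 are frozen. Fine-tuning re-applies the
same rule after replacing the head.

## The desk-scale backbone

No GPU deep-learning framework is assumed: the package ships `tiny-cnn`,
a compact, self-contained convolutional network (four 3×3 conv blocks of
8/16/32/64 channels, each followed by instance normalization and ReLU,
2×2 max-pooling between blocks, global average pooling, and a linear
softmax head; ~25k parameters, 32×32 RGB input) with hand-written
backpropagation. Instance normalization — standardizing each (sample,
channel) plane over its spatial positions, with no learnable parameters
or running statistics — plays the role the normalization layers play in
the large backbone families this package's training recipe targets: it
stabilizes scratch training and cancels per-image multiplicative
exposure within a channel, which would otherwise dominate the subtle
class cues. Convolutions are realized as im2col gathers plus one BLAS
GEMM per layer in compiled code; all gradients (including the
normalization) are verified against central finite differences in the
test suite, and one optimizer step on the head is verified against the
closed-form softmax-regression gradient. Larger families (`resnet50`,
`convnext-tiny`, `regnet-y-3.2gf`) are accepted as backbone names but
require a user-registered constructor (`register_backbone()`), since
their pretrained weights cannot be bundled.

Three desk-scale deviations from the large-model recipe are deliberate,
all chosen from single-fold diagnostics before the package's end-to-end
comparison was frozen, and all applied identically to every arm:

* **Learning rate.** A scratch-initialized tiny CNN trained for about a
  thousand steps barely moves at η_max = 3e-4, the rate appropriate for
  fine-tuning a pretrained backbone. The end-to-end protocol uses
  η_max = 1e-2 with η_min = 1e-4, annealed over each stage's planned
  epoch span (`T_max = NULL`); `train_config()`'s default remains the
  published fine-tuning recipe (η_max = 3e-4, T_max = 20).
* **Step budget.** The three 4-class arms share one configuration, but
  their training sets differ enormously (an oversampled fold can be 8×
  the thresholded fold; an undersampled one 2.5× smaller). A fixed epoch
  count would give the ROS arm an order of magnitude more optimizer
  steps. `train_config()`'s `step_budget` therefore allocates each
  4-class stage `min(60, ceiling(1000 / batches_per_epoch))` epochs —
  equal optimization effort per arm under a compute budget, with early
  stopping still active. Binary pre-training runs 8 epochs.
* **Patience.** Desk-scale validation folds are a few hundred noisy
  synthetic images, so validation loss fluctuates epoch to epoch;
  patience 10 (instead of the recipe's 5) prevents premature stops
  before the minority classes are learned.

## The synthetic corpus

`generate_corpus()` renders labeled fundus-like images so the entire
pipeline is testable without external data. Each image is a circular
bright retina field on a dark background with radial shading, dark vessel
random-walks, and an elliptical optic disc with an inner, brighter cup.
Class conditioning is analytic, so ground-truth feature locations are
known to the tests:

* **Normal**: cup-to-disc *area* ratio drawn from U(0.10, 0.30).
* **Glaucoma**: cup-to-disc area ratio from U(0.55, 0.85) — disjoint
  from and strictly above the normal range, emulating glaucomatous
  cupping.
* **DR**: 4–10 bright exudate-like blobs plus 4–10 dark hemorrhage-like
  dots scattered in the field.
* **AMD**: 6–14 mid-intensity yellowish drusen-like deposits confined to
  the central (macular) region.

Acquisition artifacts emulate a heterogeneous multi-clinic corpus: a
global multiplicative exposure factor per image (default U(0.5, 1.5),
covering under- and over-exposure), additive Gaussian pixel noise
(default sd 8 on the 0–255 scale), and a 10% fraction of images rendered
at a different resolution (×U(0.75, 1.5)) and resized later by the
pipeline. Pixels are 8-bit RGB, clipped after noise. The generator is
reproducible: identical (parameters, class sequence, seed) produce a
byte-identical corpus.

Lesion sizes, counts and colors were fixed during development so that
the generator satisfies its own learnability contract — a nearest
class-mean classifier on exposure-normalized 16×16 thumbnails beats
chance on a balanced corpus, and equalizing all class feature ranges
collapses accuracy back to chance (the null-signal configuration used in
tests). No quantitative calibration to any real corpus is claimed: the
artifact severities are free parameters.

**What passing tests do and do not show.** The synthetic classes are
linearly-detectable geometric motifs; real fundus pathology is far
subtler, label noise is absent, and inter-dataset covariate shift is
reduced to exposure/resolution jitter. End-to-end results on this corpus
validate the *machinery* (splits, training dynamics, fair evaluation,
qualitative ordering of imbalance remedies), not clinical performance.

## Preprocessing and augmentation

Images are resized to a square target (stretched by default; an optional
zero-padded mode preserves aspect ratio), scaled to [0, 1] and
standardized per channel with the fixed ImageNet-1K means and standard
deviations. Training-time augmentation applies, each with its own
probability and in this fixed order: rotation (p = 0.8, angle U(−90°,
90°), bilinear, zero fill), horizontal flip (0.5), vertical flip (0.5),
brightness/contrast jitter (0.5; `x(1+c) + 255·b` with b ~ U(±0.1),
c ~ U(±0.15), clipped), and cutout (0.5; 20 holes of up to 11×11 px
filled with zeros, hole sides uniform in 1..max, positions uniform).
Augmentation operates on the raw generated image (64 px by default)
*before* resizing to the 32 px network input, so cutout hole sizes are
interpreted on the raw scale. No augmentation is ever applied at
validation or test time, and `resize_normalize()` consumes no
randomness.

## Numerical and statistical conventions

* Degenerate one-vs-rest ratios (0/0) are reported as 0 for sensitivity
  and F1 and 100 for specificity, with a `degenerate` flag, rather than
  NaN.
* AUC is the Mann–Whitney rank statistic (ties half-weighted), exactly
  the trapezoidal area under the ROC curve; scores are the softmax
  probability of the target class.
* Cross-validation standard deviations use the population convention
  (divide by k), read as descriptive spread over a fixed set of folds;
  `sd_type = "sample"` switches to n−1.
* Fold assignment is stratified per class (with 632 AMD among ~12k
  images, unstratified folds could lack AMD entirely); fold sizes per
  class differ by at most one. The validation fold is the next fold
  cyclically after the test fold — a deterministic reading of "another
  part of the dataset".
* Argmax ties in prediction break toward the first class in canonical
  order (NORMAL, GLAUCOMA, AMD, DR); this order also disambiguates every
  class-weight vector.
* The cosine schedule is held at η_min beyond T_max (no warm restarts);
  it steps per epoch.
* Probabilities inside the loss are floored at 1e-12.
* ROC bands interpolate each fold's curve onto a fixed 101-point FPR
  grid and report pointwise mean and standard deviation of TPR.

## Problem sizes

The package's own end-to-end comparison (also run by
`scripts/acceptance.R`) uses a synthetic corpus of 2,000 normal / 300
glaucoma / 100 AMD / 800 DR images at 64×64 px — the merged-corpus
imbalance ratios at roughly 1/40 scale — with 3-fold cross-validation,
the tiny CNN, and the step-budgeted protocol above. Split-arithmetic
checks run at the full printed census (125,213 records) at the manifest
level, without materializing images.

## Known limitations

* The tiny CNN is a deliberately small scratch-trained model; absolute
  metric values on the synthetic corpus are not comparable to published
  large-backbone results on real data, only the qualitative ordering of
  the imbalance-handling arms is.
* Glaucoma sensitivity stays low at desk scale: the cup-to-disc cue is a
  few pixels after downscaling to the 32 px input and survives neither
  rotation nor cutout well at tiny-CNN capacity, so glaucoma images are
  mostly taken for normal. Normal, AMD and DR resolve cleanly, and the
  macro metrics clear their permuted-label chance bands with a wide
  margin despite the glaucoma deficit.
* ROS duplicates manifest records rather than image files; this is
  equivalent under the training loop but means "unique records" must be
  compared by path.
* Duplicate detection across pooled sources is by identifier only; no
  pixel-level deduplication is attempted.
* The resize default stretches non-square images; set
  `preserve_aspect = TRUE` if aspect distortion is a concern.
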