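---
title: "Methods: automated screening of post-anesthetic effects in mouse faces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated screening of post-anesthetic effects in mouse faces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`grimscan` screens cage-side photographs of black-furred laboratory mice
for post-anesthetic/post-surgical effects on facial expression. The label
space is deliberately binary. Grimace-scale scores exist only for a small
fraction of images in studies of this kind, far too few to fit a regression
from pixels to scores; what is available for *every* image is its
treatment and acquisition time. The package therefore assigns labels by a
treatment × time rule: time points at which group-level grimace scores were
elevated carry the `effect` label (isoflurane: 30 min; ketamine/xylazine:
30 and 150 min; castration: 30, 150, and 300 min post-procedure), and all
baselines, later time points, and untreated animals are `no_effect`
(`assign_binary_label()`). The rule is total on a fixed vocabulary and an
unknown treatment/time pair is a hard error — silent defaulting is exactly
how label noise would creep into the ground truth unnoticed.

Two assumptions follow from this labelling and shape everything else:

* **Labels are group-level.** An individual image at an `effect` time point
  may show a relaxed face. Per-image accuracy therefore has a ceiling below
  1 even for a perfect model of the latent expression, and per-(animal,
  time) confidence averaging (below) is the designed remedy.
* **Identity is a confounder.** The same animal is photographed at effect
  and no-effect time points, so any split that puts one animal's images on
  both sides leaks identity features. All evaluation here is
  subject-disjoint: animals, never images, are partitioned
  (`subject_kfold()`, `leave_one_animal_out()`).

## Pipeline stages

**Detection.** A boosted cascade of simple rectangular (Haar-like)
features, evaluated on integral images over a multi-scale sliding window,
proposes whole-face candidates. The boosted score of a short cascade of
binary stumps is coarse — on easy synthetic scenes every plausible window
saturates it — so candidate *gating* (cascade stages plus a calibrated
minimum template correlation) is separated from candidate *ranking*: among
gated windows, the normalized cross-correlation with the mean positive
training crop decides, and non-maximum suppression with the tie-break
(score, then larger area, then smaller `(x0, y0)`) picks the final boxes.
When the whole-face stage yields nothing, independent eye and ear cascades
run and their detections pass a geometric filter: R1, ear centers above eye
centers (the one rule the part-based approach is known for); R2, closest
ear–eye center distance within `[0.05, 0.6]` of image height; R3, the two
best eyes level within 0.15 of image height. R2/R3 and the fall-back box
expansion (tight part box, widened ×1.2 and extended downward ×2.0 over the
unobserved muzzle) are configurable completions — the underlying heuristic
is published only as far as R1 — with defaults chosen conservatively and
recorded in `detect_rules()`.

**Classification.** Two paths share preprocessing (bilinear resize, pixels
scaled to `[0, 1]`), the Adam optimizer with the fixed hyperparameters
(learning rate 0.001, β₁ 0.9, β₂ 0.999, ε 1e-07, decay 0), categorical
cross-entropy, batch size 100, and a fixed 50-epoch budget with a fresh
seeded permutation each epoch. "Converged after 50 epochs" is implemented
as exactly that — a budget, not an early-stopping criterion. The small CNN
(`build_own_cnn()`) stacks three 3×3 valid convolutions with 32/32/64
filters, each followed by a rectifier and 2×2 max-downsampling, then two
128-unit rectified dense layers and a 2-way softmax; pooling placement and
activations are a minimal standard completion of the published layer list,
recorded as an assumption. The transfer path (`build_head()`) trains only a
single softmax layer (`2·feature_dim + 2` parameters) on frozen
convolutional features. ImageNet backbone weights are an external artifact,
so the package ships a *stub backbone* — a frozen, seed-reproducible random
convolutional base whose final representation is average-pooled onto a 6×6
spatial grid and projected to the declared 2048-wide feature vector. The
grid pooling (rather than global pooling) keeps spatial layout in the
features; with random weights, global pooling demonstrably destroys the
class signal while grid pooling retains it. Real pre-trained weights can be
substituted through the same object interface.

Class order is fixed (`effect`, `no_effect`), confidences are post-softmax
activations, the hard label takes the larger activation, and an exact tie
goes to `effect`: for a welfare monitor the conservative error is a false
alarm.

**Balancing.** Class balancing is by uniform sub-sampling of the majority
class, applied to the *training* portion of each fold only, after
splitting. Balancing the test set would distort the reported rates; the
unbalanced test set is handled by reporting TPR and TNR alongside
accuracy. Whether balancing preceded or followed splitting in the original
protocol is unstated, so this choice is the package's own and is recorded
here.

**Confidence averaging.** `average_group_confidence()` averages the
softmax confidence vectors of all images sharing an (animal, time point)
and re-thresholds the mean. The averaged hard label follows the mean, not
the majority vote — three confident wrong frames can be outvoted by two
very confident right ones.

**Cross-treatment transfer.** `cross_treatment_design()` builds the full
3×3 train×test treatment matrix. The ketamine/xylazine subset is first
sub-sampled — by animals, until its image count matches the larger of the
two smaller subsets — because comparisons across cells are otherwise
confounded by training-set size ("same size" is interpreted as image
counts matched by animal-level sampling; matching by images directly would
split animals). Off-diagonal cells carry a subject-overlap flag whenever an
animal id appears in both treatments.

**Explanation.** `dtd_relevance()` implements deep Taylor decomposition:
the target class's *pre-softmax* activation (the softmax mixes classes and
the decomposition needs a non-negative score; which activation was
decomposed upstream is not stated, so this is the package's documented
choice) is propagated backwards. Hidden dense and convolutional layers use
the positive-share (z⁺) rule; the input layer uses the box rule with the
preprocessing range `[0, 1]`; max-downsampling routes relevance to the
winning location; rectifiers pass it through. Denominators below 1e-12 drop
that neuron's relevance with a logged warning rather than dividing by
almost-zero. For bias-free networks every layer's relevance total equals
the explained score (checked to 1e-4 relative in the tests, and exactly
against a brute-force evaluation of the redistribution formula on small
dense networks); biases absorb relevance, so for trained networks the
conservation report states the deviation instead of asserting it.

## The synthetic-data generator

`generate_dataset()` emulates the *structure* of the study data, not its
appearance: schematic dark faces (filled ellipses for head, ears, eyes with
specular glints, nose; line strokes for whiskers) on a light cage
background with floor shading, pellet distractors, Gaussian blur, and
pixel noise. Latent action-unit intensities are Gaussian, truncated to
`[0, 2]`; `effect` time points shift the per-unit means upward by a
configurable margin (default 1.0, so group means differ by at least one
scale unit), optionally weighted by per-treatment signatures so different
treatments express different facial patterns. Each action unit drives a
monotone geometric change in the render: orbital tightening closes the
eyes, ear position drops and spreads the ears, nose and cheek bulges grow
and brighten their regions, whisker change rotates the strokes. Per-animal
identity nuisance (face size, fur darkness, eye spacing, ear size, whisker
angle) is fixed across an animal's images, which is what makes
subject-disjoint splitting a meaningful test on synthetic data. Default
group sizes mirror the study roster (52 IN, 48 KXN, 19 C — all male — and
26 untreated animals, with the treatments' acquisition-time grids); the
per-animal variance components are a modeling choice, since only
group-level score distributions are published. A scene-level `occlusion`
probability hides the muzzle behind a bedding-colored block — eyes and
ears stay visible — emulating the real failure mode that motivates the
part-based detection fall-back.

What the generator does **not** model: photorealistic fur and pose,
habituation drift across repeated sessions, rater disagreement, body
posture, lighting changes. Passing tests on this generator therefore show
that the pipeline's machinery is correct and that its statistical design
(splits, balancing, averaging) behaves as intended — they do not certify
performance on real photographs.

## Numerical choices

* Convolution runs as im2col plus single-precision GEMM (the package's
  compiled backend); weights, optimizer state, and all reductions stay in
  double precision. Gradient checks against finite differences pass at the
  tolerance single-precision forward arithmetic allows (~1e-2 relative).
* The quantile convention for box statistics is linear interpolation
  between order statistics (R's default type 7); whiskers extend to the
  most extreme values within 1.5×IQR of the quartiles.
* Fold summaries use the sample standard deviation (n−1). Undefined ratios
  (a leave-one-animal-out fold whose test animal has one class only) are
  excluded from that metric's mean with a warning, never silently zeroed.
* One global seed fans out to every stochastic component (per-animal
  identities, per-image renders, splits, sub-sampling, weight
  initialization, epoch shuffles) through a stable multiplicative string
  hash (`derive_seed()`), so any subset of a run is reproducible on its
  own and all derived seeds stay below 2³¹.

## Problem sizes in the shipped tests

The test suite exercises the full pipeline at sizes a laptop CPU handles
comfortably: the synthetic-recovery experiment uses 40 animals × 2 time
points × 10 images (800 images, half the animals held out) with the small
CNN at 64×64 — a scaled-down input relative to the 224×224 default, flagged
as such in `train_config()` — plus a label-permuted control at identical
settings; the averaging-benefit experiment reuses that dataset with ten
seeded subject splits of the frozen-backbone head path; the cross-treatment
matrix uses 8 animals per treatment with distinct action-unit signatures;
detector sanity uses 200 renders with 8% muzzle occlusion against cascades
trained on 40 separate images. The acceptance script
(`scripts/acceptance.R`) re-runs the same designs from one command-line
seed.

## Known limitations

* The cascade trainer is a small-scale training path for synthetic crops;
  it is not a production cascade trainer, and its XML model format is a
  cascade-style schema of this package, not byte-compatible with other
  libraries' cascade files.
* The stub backbone makes the transfer path self-contained and testable
  but is not a substitute for ImageNet features on real images.
* Relevance propagation through an arbitrary third-party backbone is out
  of scope: for head models the tool reports feature-level relevances for
  layer types it supports and says so, rather than silently approximating.
* With a single latent dimension per action unit and near-separable
  margins, synthetic accuracies sit near 1; they are upper bounds on
  machinery correctness, not forecasts for real data.
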