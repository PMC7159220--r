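# grimscan

Automated screening of post-anesthetic and post-surgical effects from the
facial expressions of black-furred laboratory mice.

## The problem

Grimace scales score five facial action units — orbital tightening, nose
bulge, cheek bulge, ear position, and whisker change — each on a 0–2 scale,
as a welfare indicator for mice after procedures such as isoflurane
anesthesia (IN), ketamine/xylazine anesthesia (KXN), or castration (C).
Manual scoring is slow, needs trained raters, and cannot run around the
clock. `grimscan` implements the full image-analysis pipeline for the binary
variant of this problem: deciding from a cage-side photograph whether a
mouse currently shows a **post-anesthetic/surgical effect** or not, where
the ground-truth label is derived from treatment × acquisition-time (e.g.
30 min after ketamine/xylazine → effect; day 2 → no effect).

The pipeline has two learned components plus the machinery around them:

1. **Face detection** — a boosted cascade of rectangular intensity features
   (Viola–Jones style) locates the whole face; images the whole-face
   detector misses fall back to separate eye and ear detectors whose
   groups are filtered by geometric plausibility heuristics (ears must sit
   above the eyes, plausible ear–eye distances, level eyes). Accepted
   hypotheses are cropped with a configurable margin.
2. **Facial-expression classification** — either a small convolutional
   network trained from scratch (three 3×3 conv layers with 32/32/64
   filters, two 128-unit fully connected layers, 2-way softmax) or a single
   softmax layer on top of a frozen convolutional backbone. Training uses
   Adam (learning rate 0.001, β₁ 0.9, β₂ 0.999, ε 1e-07, decay 0) on
   categorical cross-entropy, batch size 100, a fixed 50-epoch budget, a
   fresh shuffle every epoch, and bilinear resizing of inputs.

Evaluation is strictly **subject-disjoint** (no mouse contributes images to
both train and test), via 10-fold cross-validation or leave-one-animal-out,
with accuracy / TPR (sensitivity) / TNR (specificity), per-(animal, time)
**confidence averaging**, cross-treatment transfer matrices, and
**deep Taylor decomposition** heatmaps that attribute each decision to
pixels (conservation-checked layer by layer).

Because the real dataset is an external download, the package ships a
seedable **synthetic face-image generator**: schematic dark-furred faces on
a light cage background whose latent action-unit intensities follow
treatment- and time-dependent profiles, with per-animal identity nuisance
and exact ground-truth bounding boxes. Every stage of the pipeline is
developed and tested against it.

## A worked example

```r
library(grimscan)

# 8 ketamine/xylazine animals, imaged at baseline and 30 min post-procedure
ds <- generate_dataset(
  synth_config(animals = c(KXN = 8),
               times = list(KXN = c("baseline", "30min")),
               images_per_group = 5, margin = 1.0),
  seed = 7)
table(ds$metadata$binary_label)
#>    effect no_effect
#>        40        40

folds <- subject_kfold(ds$metadata, k = 2, seed = 1)
cfg <- train_config(input_size = 64, epochs = 50, seed = 3)
cv <- cross_validate(ds$metadata, folds, ds$images,
                     arch = "own_cnn", config = cfg,
                     average_by = c("animal_id", "time_label"))
round(100 * cv$summary$accuracy, 1)
#> mean   sd
#>  100    0
```

The summary is the mean ± sd over folds of the per-(animal, time)
confidence-averaged accuracy, in percent: with a latent effect margin of
1.0 the two classes are nearly separable, so held-out animals are
classified almost perfectly. Dropping `average_by` gives the per-image
numbers — here 95.0 ± 7.1 — which are lower: averaging a group's softmax
confidences before thresholding filters out single bad frames.

```r
# explain one decision
img <- preprocess(ds$images[[1]], cfg)
fit <- train_classifier(balance_by_subsampling(ds$metadata, 1), ds$images,
                        "own_cnn", cfg)
map <- dtd_relevance(fit$model, img)
png::writePNG(render_heatmap(map, img, mode = "side_by_side"), "explain.png")
map$explained_score          # the pre-softmax activation being decomposed
#> [1] 0.2304903
sum(map$relevance)           # equals the score: relevance is conserved
#> [1] 0.2304903
```

A thin command-line wrapper for the whole pipeline lives at
`inst/cli/grimscan.R` (`pipeline`, `synthesize`, and `split` subcommands).

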