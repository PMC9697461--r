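---
title: "Combined box-and-line detection of mandibular fractures on synthetic panoramic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined box-and-line detection of mandibular fractures on synthetic panoramic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panfrax)
```

## The problem and the method

Mandibular fractures are usually confirmed on CBCT, but a panoramic
radiograph is cheaper and faster, so detector assistance on panoramic images
alone is clinically attractive. Two detection modalities complement each
other on such images. A bounding-box detector with class labels for the six
anatomical regions — symphysis, body, angle, ramus (the "middle" of the
mandible), condyle and coronoid process (the laterally compressed "side") —
localizes well where position is informative, which is mostly the side:
dislocated condylar fractures have a characteristic position and appearance.
It under-detects in the middle, where fracture shapes are irregular.
Semantic segmentation of the fracture *line*, by contrast, traces oblique
and shear fractures in the middle well, but cannot be trained on dislocated
condylar fractures at all: an overlap of bone contours has no crack line to
label, so displaced fractures carry box annotations but no line labels.

`panfrax` implements the combined pipeline:

1. a tooth-region U-Net segments the tooth row; its mask is dilated,
   hole-filled, and inverted into a binary weight map;
2. a fracture-line U-Net segments candidate fracture lines;
3. the weight map is multiplied into the fracture mask, erasing line pixels
   inside the tooth row — interdental seams are the dominant source of
   false fracture lines;
4. the cleaned mask is closed, speckle-filtered, and decomposed into
   connected components;
5. a box source (an external detections file, or the package's compact
   grid detector) supplies class-labeled boxes; near-duplicate boxes are
   removed by class-wise greedy NMS at IoU 0.5;
6. boxes and line components are fused with union semantics — both
   modalities are reported, with no cross-suppression;
7. evaluation matches the mixed predictions one-to-one against ground
   truth and reports precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their
   harmonic mean F1. There is no true negative in this protocol: every
   image contains a fracture, so specificity and accuracy are undefined by
   design.

## The phantom generator

Clinical radiographs cannot be redistributed, so every stage is exercised
on synthetic phantoms with known ground truth. A phantom emulates exactly
the features the pipeline logic depends on, nothing more:

* a parabolic mandibular arch rendered as a bright bone band on a darker
  background with global gradients and low-frequency random shading;
* a tooth row band above the anterior arch with periodic darker
  interdental seams (the false-positive generator for stage 3);
* fractures sampled from the six classes at the published training-set
  frequencies (24.519 / 23.237 / 29.327 / 14.583 / 6.25 / 2.083 %), with
  1 + Poisson(0.7) fractures per image (mean 1.7, matching 624 fractures
  over 360 radiographs);
* three morphologies: `oblique_gap` — a radiolucent band of 3-6 px
  crossing the bone, rendered at full contrast along the whole labeled
  polyline so the line label always traces visible image evidence;
  `shear_step` — a brightness step along the polyline plus a visible
  solid crack line; `displaced` — a duplicated, offset condylar contour
  with *no* crack line, assigned only to the condyle class. Shape
  frequencies default to 0.55 / 0.35 / 0.10; the source corpus does not
  report them, so they are configurable assumptions, not data.

Ground truth per phantom: the line mask (polylines dilated to 3 px,
displaced excluded), the tooth-polygon mask, and one box per fracture
including displaced ones. Everything is a pure function of
`(phantom_config, image index)`: each image derives a child seed, so a
dataset regenerates bit-identically.

What the phantoms do *not* model: spine and sinus shadows, restorations,
patient positioning variability, continuous texture of trabecular bone.
Passing tests therefore demonstrate that the pipeline's logic and training
machinery behave as designed, not that the networks would reach clinical
performance — the published clinical scores (precision 0.95, recall 0.87
for the combined module) require the original 420-radiograph corpus, which
is IRB-held.

## Networks

No deep-learning framework is assumed: the U-Net and the grid detector are
implemented in the package over compiled im2col convolution primitives
(3 × 3 same-padding convolutions as one GEMM, 2 × 2 max pooling,
nearest-neighbour upsampling), with exact hand-derived backpropagation
(verified against numerical gradients) and an Adam driver in R.

The U-Net follows the standard topology: per level two 3 × 3 convolutions
with the configured activation, channels doubling while max pooling halves
the resolution; the decoder upsamples, halves channels, concatenates the
same-level encoder feature, and convolves twice; a 1 × 1 head produces one
sigmoid logit map at input resolution. The activation is a configuration
toggle — `relu`, `leaky_relu`, or `elu` (default, α = 1): ELU's negative
branch `α(e^x − 1)` keeps a nonzero derivative everywhere, which is the
motivation for preferring it in the fracture-line task. Batch
normalization is omitted: at the scales the package trains, plain
conv + ELU converges stably and keeping the parameter set minimal makes
the activation comparison clean.

The loss is mean binary cross-entropy plus a soft-Dice term (weight 1 by
default). Fracture lines occupy ~1 % of the pixels, and BCE alone drives
the net to predict background everywhere; the Dice term removes that
failure mode. The optimizer is Adam; full-scale defaults mirror the
published recipe (batch 6, learning rate 1e-4, 300 epochs at 512 × 512).

The compact grid detector stands in for the full YOLOv4 stack, whose
backbone is not the object of study: three pooled conv blocks reduce the
input 8×, and a 1 × 1 head predicts per cell an objectness logit, six
class logits, and four sigmoid box parameters. Positive (object) cells are
up-weighted by `G²/(8·n_pos)` in the objectness BCE — without this the
1-vs-255 cell imbalance makes "no object anywhere" the optimum. The
detections-file path exists so the fusion stage can also be driven by any
external box source.

## Desk-scale profile and parameter choices

Tests and the acceptance script run a reduced, fixed "smoke" profile
chosen once:

* phantoms at 128 × 128 (the full-scale default is 512 × 512, the network
  input size of the published recipe; generation at the clinical
  2288-2972 px widths is supported but pointless for training here);
* fracture U-Net: depth 3, base 8 channels, ELU, 40 training phantoms,
  30 epochs, Adam at 3e-3, batch 6 — about 11 minutes on one CPU, held-out
  Dice ≈ 0.85;
* tooth U-Net: depth 3, base 4, 20 epochs — the tooth band is a single
  large blob and needs less capacity;
* postprocessing at 128 px: tooth fill with a radius-2 disc, one
  iteration, closing radius 2, minimum component size 20 px. The 512-scale
  defaults (radius 3, two iterations) are proportionally far larger at
  128 px and would erode the margin between the tooth band and nearby
  symphysis fracture lines.

Other fixed numerical choices: mask threshold 0.5 (strict inequality, so
thresholds 0 and 1 give the all-ones and empty masks); He initialization;
minibatch gradients averaged, then Adam-stepped once per batch; population
(not sample) standard deviation in line profiles; percentage rounding is
round-half-up at 3 decimals.

## The matching rule

The evaluation corpus defines TP/FP/FN but not the adjudication rule, so
the package fixes one and exposes it in `match_criteria()`: a predicted box
matches a ground-truth fracture at IoU ≥ 0.5 against its box; a predicted
line component matches when ≥ 50 % of its pixels lie within the
ground-truth line dilated by 5 px *and* ≥ 50 % of the ground-truth line
lies within the component dilated by 5 px. Matching is computed as a
maximum bipartite matching (augmenting paths) over the eligibility graph
rather than one greedy sweep: the reported TP is then exactly the best
achievable one-to-one assignment, which is also what the test oracle
(exhaustive enumeration) computes. Predictions left unmatched but eligible
only for ground truths already matched by the other modality are treated
as redundant coverage of a detected fracture and consumed rather than
counted as false positives; unmatched ineligible predictions are false
positives, unmatched ground truths are false negatives, so
`TP + FN = |GT|` always holds.

## The tone-mapping surrogate

The luminance adaptation transform of the augmentation stage is specified
behaviourally (local detail up, dark images brighter, multi-stage variant
compresses global tone); its reference algorithm is not public. The
package's surrogate is a surround-adaptive exponent transform on
normalized luminance `v` with Gaussian surround `s`:

$$\mathrm{out} = s^{\,e}\,(v/s)^{c},\qquad
  e = \frac{1}{1 + \beta\,(1-s)},\qquad c = 1 + 0.4\,\beta$$

with strength β (default 0.8, surround σ = 24 px). A dark surround drives
`e` below 1 (tone brightening) while `c > 1` amplifies the center/surround
ratio (local detail). A flat field maps to a flat field; β = 0 is the
identity. The single-stage transform applies one pass; the multi-stage
variant cascades the same pass at β/stages per stage (three by default),
which acts as global tone compression — with one stage it reduces exactly
to the single-stage transform. The surrogate satisfies the documented
behavioural contract (profile standard deviation rises on dark phantoms,
bright-half dynamic range does not expand under the multi-stage variant)
without claiming fidelity to the original algorithm.

## Known limitations

* Phantom realism is deliberately minimal (see above); Dice values on
  phantoms say nothing quantitative about clinical images.
* The grid detector is single-scale with one box per cell; overlapping
  same-cell fractures cannot both be detected. It exists to exercise the
  training/fusion path, not to rival a production detector.
* Training is single-threaded and CPU-bound; full-scale 512 × 512 training
  with the published 300-epoch recipe is supported by the same code but
  takes hours, not minutes.
* Published percentage cells that are inconsistent with their own printed
  counts (e.g. coronoid 2.084 % vs 13/624 = 2.083 %) are treated as
  typographic and excluded from exact checks; the package reports the
  recomputed values.

## A worked example

```{r example, eval = FALSE}
library(panfrax)

cfg <- phantom_config(width = 128, height = 128, seed = 11)
train <- lapply(1:40, function(i) {
  ph <- generate_phantom(cfg, i)
  list(image = ph$image, mask = ph$gt$line_mask)
})
fit <- train_segmenter(
  train,
  train_config(batch_size = 6, learning_rate = 3e-3, epochs = 30, seed = 5),
  unet_spec(input_size = 128, depth = 3, base_channels = 8, activation = "elu"))

ph <- generate_phantom(cfg, 41)
mask <- predict_mask(fit, ph$image, threshold = 0.5)
dice_coefficient(mask, ph$gt$line_mask)
```

The full pipeline on one phantom, with ground truth supplied for
evaluation:

```{r pipeline, eval = FALSE}
tooth_fit <- train_segmenter(
  lapply(1:40, function(i) {
    ph <- generate_phantom(cfg, i)
    list(image = ph$image, mask = ph$gt$tooth_mask)
  }),
  train_config(batch_size = 6, learning_rate = 3e-3, epochs = 20, seed = 6),
  unet_spec(input_size = 128, depth = 3, base_channels = 4, activation = "elu"))

res <- run_pipeline(ph$image, fit, tooth_fit,
                    box_source = NULL,
                    config = pipeline_config(se_radius = 2,
                                             fill_iterations = 1),
                    gt = ph$gt)
res$counts
c(precision = res$precision, recall = res$recall, f1 = res$f1)
```
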