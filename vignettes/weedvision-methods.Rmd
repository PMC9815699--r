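---
title: "Methods: desk-scale crop/weed detection with adaptive feature fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale crop/weed detection with adaptive feature fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(weedvision)
```

## The problem

Detecting weeds among crops in top-down field imagery is hard for two
reasons that compound each other: the objects differ strongly in scale
(crop plants are several times larger than weed seedlings), and the classes
are badly imbalanced — object-count ratios around 17:3 crop:weed are
typical for sugarbeet fields. A single-stage detector trained naively on
such data learns the crop class well and misses the small, rare weeds.

`weedvision` packages the three architectural responses to the scale
problem (a transformer encoder in the backbone, an involution-based channel
bridge between backbone and neck, and adaptively spatial feature fusion in
the head), the data-side response to the imbalance problem (pixel-level
copy-paste augmentation of weed objects), and the evaluation machinery to
measure whether any of it helps — all at a size where every experiment runs
on one CPU in minutes.

## Synthetic scenes: what they emulate and what they do not

`generate_scene()` paints a brown soil background (base RGB 118/86/62) with
Gaussian texture noise (default sd 6 intensity units), then places
green-dominant ellipses ("crops", default radius 7–12 px in a 96×96 image)
and small multi-lobed blobs of 3–5 overlapping lobes ("weeds", radius
2–4 px). The generator enforces the properties downstream code relies on:

* object pixel masks are disjoint and fully inside the image;
* candidate boxes overlapping an existing box above IoU 0.05 are rejected
  (rejection sampling, 200 attempts, explicit error naming the violated
  constraint);
* ground-truth boxes are tight around each object's painted pixels;
* plant colours are sampled so the excess-green index 2G−R−B is strictly
  positive on vegetation and negative on noise-free soil, which is what
  makes region growing and the vegetation-prior seeding meaningful.

`generate_corpus()` draws per-image counts so corpus totals hit a requested
class ratio within rounding; the default six objects per image reproduces
the 17:3 field statistic exactly whenever the total object count divides by
20 (e.g. 20 images → 102 crops : 18 weeds).

What the scenes deliberately do **not** model: perspective, illumination
gradients, plant overlap and occlusion, growth stages, soil structure such
as rows, or any photometric realism. A detector that works here has been
shown to learn shape/colour/scale separation and the pipeline plumbing has
been shown correct — nothing more. Conclusions about real field imagery
require real field imagery.

## Copy-paste augmentation

Weed segmentation uses region growing with a **fixed criterion**: a pixel
joins the region when its Euclidean RGB distance to the *seed pixel's*
colour is at most the threshold (default 60 on the 0–255 scale,
8-connectivity). A fixed criterion — rather than a running region mean —
makes the result independent of the order in which neighbours are visited,
so the operator is exactly reproducible and testable against a plain
breadth-first flood-fill oracle. The seed is the pixel of maximum excess
green inside the candidate box, the standard vegetation prior in plant
imaging; boxes whose seed has no green excess are reported as failed rather
than silently dropped.

Pasting is hard replacement under the patch mask (no illumination matching,
no feathering by default) so that the bookkeeping is exact: pasting k
patches adds exactly k weed boxes, never touches a pixel outside the pasted
masks, and preserves the original annotations verbatim. Placement is
rejection sampling against a maximum IoU of 0.05 with all existing boxes
(100 attempts, explicit error).

The split is leakage-safe by construction: synthetic images *and the
originals they were derived from* are forced into training, and only the
remaining originals are shuffled into validation and test. With the
field-scale counts (4100 originals, 1436 synthetic) an 8:1:1 target is
achievable; the invariant — no synthetic image or its source outside
training — is tested across 100 seeds. The CLI pastes into a seeded
fraction of originals (default 0.35) precisely so that free originals
remain for validation and test.

## The network blocks

All tensor code runs on plain `(H, W, C)` arrays through a small
reverse-mode autodiff tape; the heavy kernels (convolution, involution,
max-pooling) are C++ loops. Every backward rule is verified against central
finite differences in the test suite.

**Transformer encoder.** Feature-map cells are flattened to tokens; the
block is multi-head self-attention plus a SiLU MLP, each under a residual
connection with pre-norm ordering. The positional embedding is a toggle,
off by default: without positions the block is permutation-equivariant over
cells, which both matches the desk-scale use (the backbone's 3×3 top map
carries little geometry) and gives a sharp testable property. With all
attention and MLP weights zero the block is exactly the identity.

**Involution.** The K×K kernel at each position is generated from the input
at that position by a bottleneck Φ (1×1 reduce by ratio r, SiLU, 1×1 expand
to K·K·G channels) and shared across the channels of a group — spatially
specific, channel-invariant, the mirror image of convolution. The 1×1 case
used inside CFFI degenerates to learned per-position, group-shared channel
scaling; the tests pin this closed form down, along with kernel sharing
(duplicated channels in a group get identical outputs) and a brute-force
nested-loop oracle for K=3.

**CFFI.** The top backbone map is reduced by a 1×1 convolution to the
branch width (768 at full scale, scaled by the width multiplier — 96 at the
desk default 0.125), a 1×1 involution aggregates spatial information on the
reduced map, and the two branch outputs are concatenated, so the bridge
hands the neck `2 × width` channels of re-used high-level semantics instead
of a plain lossy 1×1 reduction.

**ASFF.** For each target level the other two levels are rescaled to its
shape: coarse→fine by 1×1 channel projection plus nearest-neighbour
interpolation (nearest is the bit-stable default; bilinear would be an
easy extension), fine→coarse by one octave via a 3×3 stride-2 convolution,
by two octaves via stride-2 max-pooling before that convolution. A 1×1
control convolution over the concatenated rescaled maps emits one logit map
per source; the per-position softmax gives fusion weights in [0, 1] summing
to 1 (checked to 1e-6), and the fused map is the weighted sum. A logit of
50 drives the corresponding weight within 1e-9 of 1, i.e. the head can
collapse to source selection.

## The detector

The assembly is a width/depth-scaled single-stage detector: CSP backbone
(stem + four stages; the last stage's inner bottlenecks are replaced by one
transformer encoder block when the toggle is on), PANet-style top-down +
bottom-up neck whose top lateral input is the CFFI output when that toggle
is on, and either plain 1×1 prediction convolutions or ASFF-fused heads at
strides 8/16/32. Three anchors per level; desk-scale defaults 96 px input,
width multiple 0.125, depth multiple 0.33, anchors 5–76 px matched to the
generator's object sizes. The three toggles are independent, so the
five-configuration ablation grid is constructible; the five architectures
have five distinct parameter counts.

Deliberate simplifications relative to full-scale practice, chosen for
determinism and tape size: no batch normalisation (conv + bias + SiLU), no
SPPF block, no mosaic augmentation, no pretrained initialisation.

**Loss.** YOLO-convention decoding (`(2σ−0.5)`-offset centres,
`(2σ)²`-scaled anchors), targets assigned to anchors within a factor-4 w/h
ratio on the native cell plus the nearest neighbour cell in x and y. The
loss is `1.0 · box + 1.0 · obj + 0.5 · cls`: a complete-IoU box term over
assigned anchors, binary cross-entropy objectness over all cells with the
usual 4/1/0.4 per-level balance, and binary cross-entropy classification
over assigned anchors. The box weight sits well above the full-scale
convention (0.05): with one image per optimizer step, a handful of assigned
anchors and a thirty-epoch budget, the conventional gain leaves the
localisation gradient orders of magnitude below the objectness gradient and
boxes simply never move — raising the gain to 1.0 is the desk-scale
rebalance that makes localisation learnable in minutes. The box gradient
with respect to the four raw activations is taken by central finite
differences through the CIoU (step 1e-4, accurate to ~1e-8); the
cross-entropy gradients are analytic. Non-finite losses abort with the
offending component named.

**Training.** Plain SGD with momentum 0.9, constant learning rate
(default 5e-3), one image per step, single CPU thread, gradients clipped
to a global L2 norm of 5 before each update — without normalisation
layers an occasional outlier step otherwise inflates the activations and
the run never recovers. Everything is seeded: weight initialisation by
the model config's seed, data order by the training seed — two runs with
the same seeds produce bit-identical loss curves, which is asserted in
the tests.

## Problem sizes and numerical choices

The test suite and the worked examples run at sizes chosen so the whole
suite completes comfortably on one CPU: 96×96 scenes, width 0.125
(channels 8–128), the training smoke study 50 images × 30 epochs with a
10-image held-out split (a few minutes), the ablation run 16 training and
6 validation images for one epoch per configuration. The smoke study's
bar is deliberately modest — final loss below the initial loss and
held-out mAP@0.5 above the untrained model's — because thirty epochs at
this scale demonstrate that the machinery learns, not that it is a good
field detector; in the reference run validation mAP@0.5 moves from ~0.001
(untrained, chance-level box soup) to ~0.17, with the large crop class
learned first (recall ≈ 0.96) and the small weed class still weak, which
is exactly the small-object asymmetry the architecture work targets at
full scale.

Numerical conventions worth stating:

* Softmax weight normalisation is checked to 1e-6 absolute; weight-sum
  deviations at that level come from the exp/normalise rounding.
* AP uses the all-points precision envelope (the exact discretization of
  the integral over recall), not 11- or 101-point sampling; confidence
  ties are broken by detection input order (R's stable `order`), and this
  is documented as this package's convention rather than inferred from
  anyone else's implementation.
* IoU of any zero-area box is 0 by convention; AP of a class with no
  ground truth is reported `NA` ("undefined"), never 0, and excluded from
  the mAP mean.
* The mAP@0.5:0.95 sweep includes both endpoints (0.5 and 0.95, step
  0.05, ten thresholds).
* Region growing bounds region size (`max_region_pixels`) and errors
  loudly when exceeded; the degenerate uniform image grows to the full
  frame.

## Known limitations

* The synthetic scenes are a correctness instrument, not a realism
  instrument (see above); reported desk-scale metrics say nothing
  quantitative about field performance.
* The weed class at desk scale remains under-detected after the short
  smoke training; closing that gap would need longer schedules, more
  capacity, or anchor retuning — out of scope for a correctness suite.
* Checkpoints are RDS files of flattened parameters; there is no
  cross-version weight-format guarantee.
* The CIoU finite-difference gradient, while deterministic and accurate,
  costs eight extra CIoU evaluations per assigned anchor; at full scale an
  analytic gradient would be preferable.
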