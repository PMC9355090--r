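---
title: "Screening plug-tray seedlings from side-view images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening plug-tray seedlings from side-view images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeedlingScreen)
```

## The problem

Leafy-vegetable seedlings raised in dense plug trays (e.g. 72-hole trays)
cannot be screened from above: neighbouring leaves interlock and single
plants cannot be segmented. A transplanting robot can instead photograph the
seedlings it has just gripped from the side — several stations per frame,
each station showing one seedling (or an empty gripper after a failed pick)
against a light, neutral background. Each station must then be classified as

* **healthy** — transplant it,
* **unhealthy** — wilted, under-grown, substrate lost, or short of the
  "three leaves and one heart" maturity criterion; remove it,
* **none** — no seedling was picked; the station is empty.

`SeedlingScreen` implements the full software side of that loop: HSV
color-threshold background removal, two interchangeable classifiers (a
rule-based pixel-area screen and a three-class residual convolutional
network), confusion-matrix evaluation, and a synthetic image generator that
makes every stage testable without any camera.

## Color model and background removal

Images are 8-bit RGB arrays (`H x W x 3`, origin top-left). The conversion
to HSV is the standard hexcone model computed channelwise: with
$R' = R/255$ (similarly $G'$, $B'$), $C_{\max} = \max(R',G',B')$,
$C_{\min} = \min(R',G',B')$ and $\Delta = C_{\max}-C_{\min}$,

$$H =
\begin{cases}
0^\circ & \Delta = 0\\
60^\circ\,\big((G'-B')/\Delta\big) & C_{\max}=R'\\
60^\circ\,\big((B'-R')/\Delta + 2\big) & C_{\max}=G'\\
60^\circ\,\big((R'-G')/\Delta + 4\big) & C_{\max}=B'
\end{cases}
\qquad
S = \begin{cases}0 & C_{\max}=0\\ \Delta/C_{\max} & \text{else}\end{cases}
\qquad
V = C_{\max}.$$

Three numerical conventions matter and are fixed throughout the package:

* **Half-range hue.** Results are stored as $H/2 \in [0,180]$,
  $S\cdot255$, $V\cdot255$, the encoding that 8-bit HSV threshold tables
  use. The red branch of $H$ can be negative (magenta-ish pixels); it is
  wrapped by adding $360^\circ$ *before* halving so hue always lands in
  the table's domain.
* **Rounding.** Scaled channels are rounded half away from zero. Base R's
  banker's rounding would make masks platform-dependent in rare ties;
  this keeps them bit-reproducible.
* **Ties in the hue branch.** When several channels share the maximum the
  first matching branch in the order $R', G', B'$ applies; the $\Delta=0$
  case always yields $H = 0$.

Ten named color ranges (black, gray, white, red, orange, yellow, green,
cyan, blue, purple) ship as a versioned JSON resource
(`inst/extdata/hsv_color_table.json`) so deployments can override them
wholesale. Printed reproductions of this classic table are often garbled
(one commonly circulated version carries eleven hue columns for ten
labels); the shipped file is the consistent canonical reconstruction — red
carries the two hue intervals 0–10 and 156–180, "ash" is gray
(S 0–43, V 46–220) and "young" is cyan (H 78–99) — and we flag explicitly
that this reconstruction is an interpretation of an ambiguous original.

Background removal keeps every pixel inside the union of the
**plant-color mask** (orange ∪ yellow ∪ green ∪ cyan ∪ blue — everything
chromatic a seedling can show against a white/gray background) and the
**substrate mask** (black: $V \le 46$), and paints the rest white. The
classical two-step composition — black-background intermediate, mask
inversion to transparency, summation onto white — is algebraically a single
masked overlay, so `extractSeedling()` implements the single pass and
offers the black-background intermediate only as a debugging attribute.
Because pure white falls in no extraction range, extraction is idempotent.

Frames holding several seedlings are cut into equal-width vertical slices,
numbered left to right; the division remainder goes to the rightmost slice
so the slices always reconstruct the frame exactly. Whether one crops
before or after background removal does not change the result (the masks
are pixelwise), so the pipeline removes the background first. Network
inputs are resized to 224 × 224 with a direct bilinear resize — no aspect
preservation, the common preprocessing for classification networks.

## The rule-based screen

`measureAreas()` thresholds the **yellow ∪ green** pixels (leaf tissue; a
deliberately narrower set than the five-color extraction union, because
leaf measurement should not count blue-ish or cyan artifacts) and the
**black** pixels (substrate), denoises both binary images, and counts
foreground pixels. The denoise chain is: dilation then erosion with a
3 × 3 elliptical (diamond) element, then a 5 × 5 Gaussian
($\sigma = 1.1$, the standard bandwidth for that kernel size) followed by
re-thresholding at the 127 mid-level, which restores a strictly binary
mask deterministically. These are minimal denoisers — just enough to close
one-pixel gaps and delete isolated noise pixels — and all of them are
configurable through `morphologyConfig()`. Areas are counted *after* the
full denoise chain (the alternative, counting before smoothing, is
ambiguous in the source protocol; counting the final mask is what the
verdict is actually based on).

The verdict is a total function of the two areas:

| leaf area | substrate area | verdict |
|---|---|---|
| 0 | 0 | none |
| ≥ 2,300 | ≥ 1,300 | healthy |
| otherwise | | unhealthy |

Both thresholds are inclusive and expressed in pixels of the nominal
640 × 480 capture; they are parameters (`screeningThresholds()`) because
they are camera- and distance-specific. The empty-station test is strict
zero by default; a configurable `epsilon` tolerates sensor noise if a
deployment needs it. The three regions partition the nonnegative quadrant,
and growing either area can never demote a healthy verdict — both
properties are tested.

The rule-based screen cannot see leaf *count* or arrangement, only area;
a seedling with ample area but fewer than three true leaves will be
mislabelled healthy. That blind spot is inherent to the method and is the
reason the learned classifier exists.

## The residual network classifier

Two architectures are provided.

**Transfer network.** The standard batch-normalised 18-layer residual
classification backbone — 7 × 7 stride-2 stem, 3 × 3 max pooling, four
stages of two residual blocks at 64/128/256/512 channels, bias-free
convolutions, projection shortcuts on downsampling — with the 1000-way
head replaced by a 3-way fully connected layer. This network has exactly
**11,178,051** trainable parameters (backbone 11,176,512 plus
512 × 3 + 3 = 1,539 for the head), which the test suite asserts.
Pretrained backbone weights are *not* redistributed with the package;
`buildTransferNet()` initialises randomly, and fine-tuning from a
pretrained checkpoint is done by loading weights into `@params` with
`reinitWeights = FALSE`.

**Custom network.** A narrow variant for the same 224 × 224 input: a
3 × 3 stride-3 stem (16 channels, no pooling) and five stages of two
residual blocks at 16/32/64/128/256 channels. The published description of
this variant fixes only kernel sizes, channel widths and per-stage output
sizes (74, 25, 9, 5, 3); strides, shortcut types and bias usage are left
open. We use bias-free convolutions with batch norm, projection shortcuts
on any channel/stride change, and the unique stride assignment consistent
with the printed output chain: stem stride 3 pad 0 (224 → 74), stages 2–3
stride 3 pad 1 (74 → 25 → 9), stages 4–5 stride 2 pad 1 (9 → 5 → 3).
Under this reading the network has 2,800,659 parameters. The total of
1,230,275 sometimes quoted for this table cannot be reconciled with any
standard reading (even counting only one block per stage, or removing all
projections, does not produce it), so the package reports its own count
rather than forcing an inconsistent number; the per-stage output sizes,
which *are* unambiguous, are asserted exactly in the tests.

**Engine.** The forward/backward passes run in compiled code
(Rcpp/RcppArmadillo): convolutions as im2col + GEMM, batch normalisation
over the minibatch, ReLU, max/global-average pooling, residual addition,
and softmax cross-entropy. Gradients are validated in the test suite
against central finite differences on a small network (agreement to
~1e-9). Training uses Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) with
mini-batches of 32; every random draw — weight initialisation, shuffling,
split assignment — derives from the single `seed` in `trainingConfig()`.

Two batch-norm details are deliberate:

* **Running statistics** default to *cumulative* averages of the
  per-batch statistics rather than an exponential moving average, and the
  statistics are **recalibrated after every epoch** by a gradient-free
  pass over the training split with the epoch's final weights. With short
  training runs (tens of optimiser steps) EMA statistics lag the weights
  badly and inference-mode accuracy misrepresents the model;
  recalibration makes the validation curve, the best-epoch selection and
  the saved model consistent. Long runs can switch to EMA via
  `bnMomentum`.
* **Checkpoint selection** keeps the epoch with the highest validation
  accuracy, ties broken by lower validation loss.

Training aborts with a diagnostic on a non-finite loss. Prediction is the
arg-max of the three logits with scores normalised by softmax; exact ties
resolve to the lowest class index (healthy, then unhealthy, then none) —
an arbitrary but documented and deterministic rule.

Learning-rate behaviour follows the usual pattern, which the tests check
qualitatively: at 1e-3 the per-step loss curve is noisy ("glitchy"), at
1e-5 it is visibly smoother (fewer sign flips in its first differences),
at the price of slower convergence.

## Dataset handling and augmentation

Manifests are plain CSVs (`path,label,split`). `splitDataset()` assigns
train/validation/test per class at 60/20/20 by floor-then-largest-remainder
(ties favour train, then val), so per-class counts deviate from the exact
fractions by at most one image — 1,085 images split as 651/217/217. The
split is an exhaustive partition, stratified, and deterministic per seed;
all three classes must be present (an empty class is an error, since a
three-way classifier cannot be trained without it).

`augmentImage()` composes horizontal flip, shear (≤ 25°), rotation (≤ 20°)
and horizontal/vertical shifts (≤ 0.3 of each dimension) into a single
affine map about the image center, resampled bilinearly in one pass;
vacated pixels are filled with white to match the extracted-image
background. A zero-magnitude configuration is the exact identity, and a
fixed seed gives bit-identical output. Augmentation exists to expand
under-represented classes offline (it is how a scarce defective-seedling
class is typically grown to parity); the training loop itself does not
augment.

## The synthetic generator

`renderSeedling()` draws, on a light neutral background with per-pixel
jitter (kept inside the white HSV range so extraction removes it), a dark
substrate block at the bottom center and a number of green elliptical leaf
blobs above it. Pixel sets are chosen by ordering candidate ellipse pixels
by normalised radius and keeping exactly the target count, so rendered
areas equal their targets *exactly* and the record's ground truth is the
rendered truth. Leaf colors are jittered within the green hue range;
substrate pixels stay below the black range's value bound.

The generator's label rule is: **none** for an empty frame; **healthy**
iff leaf area ≥ 2,300 *and* substrate area ≥ 1,300 *and* at least three
leaf blobs; otherwise **unhealthy**. The blob count is an explicit proxy
for the three-leaves-one-heart criterion — the real criterion is botanical
and has no geometric definition here. Class parameters (fixed before any
end-to-end results were measured, and not revisited):

* healthy: both areas uniform in [1.2, 1.8] × their thresholds,
  3–4 blobs;
* unhealthy: one of three defect modes — leaf deficit (leaf area in
  [0.3, 0.8] × threshold), substrate loss (substrate in
  [0.15, 0.8] × threshold), or wilt (flattened blobs near the substrate
  plus a leaf deficit) — with the other area healthy, 2–4 blobs;
* none: background only.

Unhealthy renders always carry an *area* deficit of at least 20%, never a
blob-count-only deficit: the rule-based screen cannot see blob counts, and
the margin-separated regime is exactly the one in which the screen should
reach 100% agreement with the generator — a property the acceptance suite
asserts on 300 images.

What the generator does **not** emulate: leaf occlusion of the substrate,
roots protruding outside the plug, specular highlights, uneven
illumination, interlocking neighbours, or borderline seedlings whose areas
straddle the thresholds. Passing the synthetic suites therefore
demonstrates that the measurement and learning machinery is correct and
well-calibrated on clean, margin-separated inputs; it does not certify
field accuracy on real captures, where exactly those effects dominate the
error rate.

## Problem sizes used by the test suite

The end-to-end check trains the custom network on 300 synthetic images
(100 per class, 60/20/20 split, fixed seed), 10 epochs at learning rate
1e-4, on background-removed crops — the same preprocessing the frame
pipeline applies — and requires at least 95% held-out accuracy plus 100%
rule-based agreement on the same renders. These sizes are the package's
own reduced-scale validation choice: large enough that all three classes
and all three defect modes appear in every split, small enough to run
routinely on a single CPU. Unit tests use much smaller canvases and a
12 × 12 network for the finite-difference gradient oracle.

## Known limitations

* The color table assumes the white/gray background of a lit capture box;
  colored backgrounds would need a table override.
* The rule-based screen is blind to leaf count and arrangement (see
  above) and to substrate occlusion by leaves, which in real data causes
  healthy seedlings to be under-measured.
* The network trains from random initialisation here; with small real
  datasets, fine-tuning pretrained backbone weights is the intended use
  of the transfer architecture, and the package deliberately does not
  bundle such weights.
* The compiled engine targets small CPU-trainable networks; it does not
  use GPUs and does not implement operators beyond what these two
  architectures need.
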