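# SeedlingScreen

Selective screening of plug-tray vegetable seedlings from side-view
images, for the software side of robotic transplanting: decide, station
by station, whether the seedling a gripper just picked is **healthy**
(transplant it), **unhealthy** (remove it), or **none** (the pick
failed and the station is empty).

Leafy seedlings raised in dense 72-hole plug trays cannot be segmented
from a top view — neighbouring leaves interlock — so screening happens on
side-view captures of the gripped seedlings, several stations per
640 × 480 frame, against a light neutral background.

## What the package implements

**Background removal by HSV thresholding.** RGB is converted to HSV with
the standard hexcone model (H = 0°/60°·((G′−B′)/Δ)/… by the maximal
channel, S = Δ/C_max, V = C_max) stored in the 8-bit half-range encoding
(H/2 ∈ [0,180], S·255, V·255). A pixel is kept iff it falls in the union
of the plant-color ranges (orange ∪ yellow ∪ green ∪ cyan ∪ blue) or the
black substrate range of a ten-color threshold table shipped as an
overridable JSON resource; everything else becomes white.

**Rule-based screen.** Leaf pixels (yellow ∪ green) and substrate pixels
(black) are thresholded, denoised (3 × 3 dilation/erosion, 5 × 5 Gaussian,
mid-level re-threshold) and counted. Verdict: both areas zero → `none`;
leaf ≥ 2,300 px **and** substrate ≥ 1,300 px → `healthy`; otherwise
`unhealthy`.

**Residual-network screen.** A three-class 18-layer residual network —
either the standard transfer backbone with its 1000-way head replaced by
a 3-way head (exactly 11,178,051 trainable parameters) or a compact
16→256-channel variant with per-stage output sizes 74/25/9/5/3 on
224 × 224 inputs. Training (cross-entropy, Adam, mini-batch 32) and
inference run in compiled Rcpp/Armadillo code on plain CPUs; gradients
are verified against finite differences in the test suite.

**Evaluation.** 3 × 3 confusion matrices (rows = forecast,
columns = true), per-class TP/FP/FN/TN, precision = TP/(TP+FP),
recall = TP/(TP+FN), F1 = 2PR/(P+R), overall accuracy = trace/total.

**Synthetic data.** A generator that renders side-view seedling images
(green leaf blobs over a dark substrate block on a jittered light
background) with *exact* ground-truth pixel areas and rule-derived
labels, so every stage is testable without a camera.

**Pipeline.** `screenFrame()` cuts a multi-seedling frame into station
crops, extracts each seedling, classifies with either method and returns
per-station verdicts with removal flags (optionally logged as JSON
lines).

## Worked example

Entering the published 900-seedling screening result of the network
model as a confusion matrix and recomputing its metrics:

```r
library(SeedlingScreen)
cm <- asConfusionMatrix3(matrix(c(439, 12, 0,
                                  11, 138, 0,
                                  0, 0, 300), nrow = 3))
cm
#> ConfusionMatrix3 (rows = predicted, columns = true)
#>            true
#> predicted   healthy unhealthy none
#>   healthy       439        11    0
#>   unhealthy      12       138    0
#>   none            0         0  300
#> accuracy: 97.44%, misclassified: 23 of 900
print(metricsTable(cm), digits = 4)
#>       class  TP FP FN  TN precision recall     f1
#> 1   healthy 439 11 12 438    0.9756 0.9734 0.9745
#> 2 unhealthy 138 12 11 739    0.9200 0.9262 0.9231
#> 3      none 300  0  0 600    1.0000 1.0000 1.0000
```

So 97.44% of the 900 seedlings are classified correctly and 23 are not;
healthy precision/recall are 97.56%/97.34%, unhealthy 92%/92.62%, and
the empty-station class is perfect.

Rendering a synthetic seedling and screening it by pixel areas:

```r
set.seed(42)
r <- renderSeedling(synthParams(leafBlobCount = 3,
                                targetLeafArea = 3000,
                                targetSubstrateArea = 1500))
screenPhysical(r$image)
#> ScreeningResult: healthy (leaf 3000 px, substrate 1498 px)
```

The measured leaf area recovers the rendered 3,000 px exactly and the
substrate within 2 px; both clear their thresholds (2,300 / 1,300), so
the verdict is `healthy`.

Training the compact network on a generated dataset and screening a
frame end to end:

```r
man <- generateDataset(100, seed = 11, outDir = "synth")
x   <- loadImageBatch(man$path, 224, extract = TRUE)
net <- trainNet(buildCustomNet(), man,
                trainingConfig(learningRate = 1e-4, epochs = 10, seed = 7),
                tensors = list(x = x, y = match(man$label, seedlingClasses())))
verdicts <- screenFrame(readImageRGB("frame.png"), method = "cnn", net = net)
```

A command-line front end over the same functions is installed at
`inst/cli/seedlingscreen.R` (subcommands `synth`, `extract`,
`screen-physical`, `train`, `predict`, `evaluate`, `run`).

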