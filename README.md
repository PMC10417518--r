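# cattleseg

Semantic segmentation of cattle in multi-animal farm scenes, for
precision-livestock researchers who need per-pixel animal regions (and their
relation to pens, feeding or drinking areas) rather than bounding boxes.
The package implements an improved DeepLabV3+ network family and everything
around it — metrics, annotation ingestion, fog-robustness evaluation, a
procedural scene generator and a seeded training loop — entirely in R, with
the numerical kernels (convolution, batch normalisation, bilinear
resampling, attention) compiled from C++ inside the package.

## The model

Three classes are segmented: background (0), dairy cow (1) and beef cattle
(2). The network family is:

* **Backbone** — the first four down-sampling groups of MobileNetV2
  (inverted-residual bottlenecks: 1×1 expansion, 3×3 depthwise, 1×1 linear
  projection). The two deepest stages run at stride 1, the last with atrous
  rate 2, so the output stride is 16 instead of 32: a 480×480 input yields a
  30×30×320 deepest map, with skip maps exposed at 1/2, 1/4 and 1/8
  resolution.
* **Encoder head** — atrous spatial pyramid pooling (ASPP): a 1×1 branch,
  3×3 atrous branches at rates 6/12/18, and a global-pooling branch,
  concatenated and projected to 256 channels.
* **Decoder (layer-by-layer)** — four 2× bilinear up-samplings and three
  fusion points: the encoder output is repeatedly up-sampled and
  concatenated with the 1/8, 1/4 and 1/2 skip maps (each reduced by a 1×1
  convolution), refined by 3×3 convolution + batch norm + ReLU; after the
  last fusion two stacked 3×3 convolutions precede a 1×1 classifier and a
  final 2× up-sampling, so logits come out at input resolution.
* **Squeeze-and-excitation attention** — after each fusion, channel weights
  `HSigmoid(FC2(HSwish(FC1(GAP(x)))))` in [0, 1] rescale the fused map.

The ablation grid is selected by `modelVariant()`: `m2Variant()` (simple
one-fusion decoder), `m2uVariant()` (layer-by-layer decoder), `impVariant()`
(layer-by-layer + SE; the full model).

Evaluation uses the standard confusion-matrix statistics, with rows as
ground truth and columns as prediction:

    PA   = trace(C) / sum(C)
    CPA_c = C[c,c] / colsum_c(C)        MPA  = mean_c CPA_c
    IoU_c = C[c,c] / (rowsum_c + colsum_c - C[c,c])
    MIoU = mean_c IoU_c

Fog robustness is probed with the atmospheric-scattering composite
`I = J·t + A·(1−t)`, `t = exp(−β·depth)`, applied to a configurable fraction
of the test set (images only — masks are never altered).

## Worked example

Train the full variant at desk scale (96×96 synthetic scenes, compact
channel widths) and score it on clear and fogged held-out scenes:

```r
library(cattleseg)

recipe <- sceneRecipe(seed = 101)                 # 96x96, 1-4 animals, railings
train  <- generateScenes(recipe, 200)
heldRecipe <- recipe; heldRecipe@seed <- 9901L
held   <- generateScenes(heldRecipe, 40)

model <- buildModel(impVariant(), deskNetworkOptions(seed = 11))
fit   <- trainModel(model, train, deskTrainConfig(seed = 11L), verbose = TRUE)

proto <- fogTestProtocol(held, fraction = 0.5, seed = 11)
evaluateModel(model, proto$sunny)
evaluateModel(model, proto$foggy)@miou
```

Output of this exact run (about 8 minutes on one CPU):

```
MetricsReport: PA 0.9917  MPA 0.9747  MIoU 0.9488
  background   CPA 0.9951  IoU 0.9908
  cow          CPA 0.9606  IoU 0.9151
  beef         CPA 0.9684  IoU 0.9403
[1] 0.1615469
```

Read: on clear scenes 99.2% of pixels are labelled correctly and the mean
per-class overlap with the true animal regions is 94.9%; the same model
scored on heavily fogged copies of the same scenes collapses to 16.2% mean
IoU — the degradation the fog protocol is designed to expose (the model was
trained on clear scenes only).

`runExperiment()` wraps the whole pipeline (generate → split → fog → train →
evaluate → metrics tables, loss trace, overlays, hashed manifest) driven by
one YAML config, and `inst/cli/cattleseg` exposes the subcommands
`generate | convert | fog | split | train | eval | ablate | run`.

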