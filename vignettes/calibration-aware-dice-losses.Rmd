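---
title: "Calibration-aware Dice-family losses: models, choices and limitations"
author: "SegCalib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration-aware Dice-family losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SegCalib)
```

## The problem

Semantic segmentation of biomedical images is a per-pixel classification
task in which the structure of interest — a tumour, cell nuclei, retinal
vessels — typically occupies a small fraction of the image. Networks
trained with the soft Dice (DSC) loss handle this class imbalance well and
dominate practice, but they are notoriously *overconfident*: softmax
outputs concentrate at 0 and 1 even where the prediction is wrong, so the
probability map carries no usable uncertainty. Cross-entropy training is
well calibrated but under-segments small structures. Neither behaviour is
acceptable when a clinician needs both a good segmentation and an honest
confidence map.

## The model: exponentiating the soft error terms

Write the per-class soft confusion sums over pixels $i$,

$$\mathrm{tp}_c = \sum_i p_{0i,c}\,y_{0i,c},\qquad
  \mathrm{fp}_c(\gamma) = \sum_i (p_{0i,c}\,y_{1i,c})^{\gamma},\qquad
  \mathrm{fn}_c(\gamma) = \sum_i (p_{1i,c}\,y_{0i,c})^{\gamma},$$

where $p_{0i,c}$ is the predicted probability of class $c$ at pixel $i$,
$p_{1i,c} = 1 - p_{0i,c}$, and $y_{0},y_{1}$ are the one-hot indicator and
its complement. The calibration-aware Dice loss implemented by
`dscppLoss()` is

$$L_{\mathrm{DSC++}} \;=\; 1 - \frac1C \sum_{c=1}^{C}
  \frac{2\,\mathrm{tp}_c}
       {2\,\mathrm{tp}_c + \mathrm{fp}_c(\gamma) + \mathrm{fn}_c(\gamma)}.$$

At $\gamma = 1$ this is *exactly* the Dice loss (the test suite asserts
agreement to $10^{-12}$ against an independent implementation built on the
overlap form $2\sum p y / (\sum p + \sum y)$). For $\gamma > 1$ each
per-pixel error product — which lies in $[0,1]$ — is shrunk the more, the
smaller it is: a confident error ($q \approx 1$) keeps its full weight
while a hesitant one ($q \approx 0.5$) is discounted by $q^{\gamma}$. The
optimum therefore no longer rewards pushing probabilities to the extremes
in uncertain regions; it penalises overconfident mistakes selectively. The
same substitution drops into every Dice-based compound loss (Tversky,
focal Tversky, Combo, unified focal), giving the `"*++"` entries of the
loss registry.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `gammaPP` | exponent on soft FP/FN products | 2 | the value found by grid search to maximise calibration gain without hurting overlap; `1` recovers each original loss |
| `focalAlpha`, `focalGamma` | focal-loss class weight and focusing exponent | 0.5, 2 | standard optimal settings for this loss family |
| `tverskyAlpha`, `tverskyBeta` | FP / FN weights of the Tversky index | 0.3, 0.7 | recall-favouring standard setting |
| `ftGamma` | focal-Tversky exponent (loss uses $1/\gamma$) | 4/3 | standard |
| `comboAlpha`, `comboBeta` | CE/Dice mix; positive-class CE weight | 0.5, 0.5 | standard |
| `ufLambda`, `ufDelta`, `ufGamma` | unified-focal mixing, asymmetry, focusing | 0.5, 0.6, 0.5 | standard |
| `smoothEps` | additive smoothing of every ratio | 1e-6 | prevents 0/0 on empty classes while moving the hand-worked values by less than 1e-5 |
| `includeBackground` | background channel in region-loss averages | `TRUE` | the class sum as written runs over all channels; both conventions are supported because published implementations differ, and the worked examples state which they use |

Gamma values in $[0.5, 1)$ are accepted (the grid search explores them)
but warn, since the penalty mechanism presumes $\gamma \ge 1$.

## Numerical choices

* Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ before any
  logarithm; $0^{\gamma}$ is defined as 0 (continuous extension) so exact
  0/1 inputs are legal.
* Per-pixel probability sums must equal 1 within $10^{-6}$; inputs are
  renormalised only on request, never silently.
* Argmax decoding breaks ties towards the lowest class index; softmax
  thresholding labels a tie `s == T` as foreground so that `T = 0.5`
  matches argmax for binary maps.
* Every loss has a hand-derived analytic gradient with respect to the raw
  probability entries (the "differentiable" route used by the trainer via
  the softmax chain rule); a central finite-difference oracle
  (`numericalGradient()`) verifies all of them to a relative error of
  $10^{-4}$ in the test suite.
* The modified CE inside the Combo loss is written on the foreground
  channel (the binary form as published); for more than two classes it is
  averaged one-vs-rest over foreground channels. The leading $-1/N$ is
  taken to distribute over both log terms — any other reading is unbounded
  below.
* In the asymmetric focal component of the unified focal loss the
  published subscripts are ambiguous; we read the focal term's probability
  as the true-class probability of the pixel. Both endpoint identities
  ($\lambda \in \{0,1\}$) and a brute-force per-pixel oracle pin the
  implemented reading down in the tests.
* The focal loss is implemented exactly as printed, which makes it equal
  to cross entropy at `focalGamma = 0` (with unit `focalAlpha`); prose
  descriptions sometimes state the equivalence at 1.
* The softmax-thresholding indicator is implemented as *foreground iff
  `s >= T`*: the printed indicator in the source literature reads `s < T`,
  which contradicts both the stated special case `T = 0.5` (argmax) and
  the stated behaviour that higher thresholds favour precision, so the
  behaviourally consistent direction is used and the discrepancy noted
  here.

## The synthetic generator

`generateDataset()` emulates three class-imbalanced regimes: elliptical
**blobs** (lesion/nucleus-like), connected curvilinear **vessels** of
width 1–3 px grown as momentum random walks with branches rooted on the
existing tree (retina-like), and a three-class **organ** with an internal
lesion. Images carry class-dependent intensity (0.3 / 0.7 / 0.9) plus
Gaussian noise; everything is deterministic given the mandatory seed.

`simulatePredictor()` produces a *well-calibrated* reference predictor:
per-class scores are signed Euclidean boundary distances (exact separable
distance transform, cross-checked against an independent image-analysis
library) passed through a softmax with length scale `tau`, so confidence
is graded near boundaries and high in structure interiors. Miscalibration
is injected in two controlled ways: clustered **flips** make a fraction of
pixels *low-confidence errors* (the wrong class wins with probability
0.55–0.75), and the **sharpening** exponent `k` raises probabilities to
the `k`-th power and renormalises — overconfidence that leaves every
argmax unchanged. Sharpening therefore worsens NLL and Brier while hard
Dice is provably untouched, which is the mechanism the calibration metrics
must detect.

What the generator does *not* emulate: anatomical texture, imaging
physics, annotation noise, or inter-image correlation. Tests passing on
this data show that the losses, metrics and harness behave as specified —
not that any particular clinical performance would be attained.

## The desk-scale training harness

The harness trains a deliberately tiny two-level U-Net (two 3×3 encoder
convolutions, 2×2 max-pool, one bottleneck convolution, nearest-neighbour
upsampling with skip concatenation, 1×1 softmax head; Xavier
initialisation; hand-written im2col backpropagation) using the standard
protocol of this literature: SGD, batch size 1, initial learning rate 0.1,
z-scored inputs, on-the-fly augmentation with probability 0.15 (scaling
0.85–1.25×, rotation ±15°, mirroring, elastic deformation, brightness
0.5–2×), learning-rate reduction ×0.1 after 25 non-improving validation
epochs and early stopping after 50, with an epoch cap (default 100) on
top. Instance normalisation is omitted at this scale; inputs are z-scored
per image. Two adaptations keep the protocol meaningful on 64×64 images:

* the elastic-deformation amplitude range (specified as $\alpha \in
  [0,900]$ for 512-px images) is scaled by `min(shape)/512` so the
  *relative* deformation matches; unscaled fields displace by a quarter of
  the image and can destroy a half-trained tiny model in one batch-size-1
  step;
* the default experiment uses the **vessel** generator at noise 0.2
  (half the foreground contrast). This places the attainable Dice of the
  tiny U-Net near 0.85 — the difficulty regime of the real retinal
  benchmark on which the exponent was originally tuned. On a trivially
  easy task (blobs at low noise) the model reaches Dice ≈ 0.99 and there
  are no uncertain structures left for calibration to act on.

The canonical desk-scale comparison — 200 vessel images, splits
64%/16%/20% (the 80/20 development/test split with the development set
split 80/20 again), 10-epoch cap, three seeds, $\gamma \in \{1, 2\}$ —
runs in minutes on one CPU and reproduces the *direction* of the full-scale
result: median test NLL roughly halves under $\gamma = 2$ while the median
Dice shift stays within 0.05. Magnitudes are not comparable to GPU-scale
training and are not asserted anywhere.

`gammaGridSearch()` reuses one dataset, split and initialisation across
the grid (default $\gamma \in [0.5, 5]$ in steps of 0.5) so rows differ
only in the loss.

## Softmax thresholding

After training, `applyThreshold()` replaces the argmax decision with a
cutoff `T` on the target-class softmax output; `thresholdSweep()` scores
recall/precision/Dice across `T` ∈ 0.05…0.95 with bootstrap confidence
intervals over images. Because the predicted-positive set shrinks
monotonically in `T`, recall is non-increasing and the `T = 0.5` row
equals the argmax metrics — both asserted in the tests. This
post-processing is only informative when the probabilities are graded;
for an overconfident predictor the sweep is flat, which is precisely the
practical argument for calibration-aware training.

## Evaluation conventions

NLL shares the cross-entropy implementation verbatim; the Brier score is
the mean squared error over all pixel–class entries. Hard overlap metrics
come from argmax-binarised masks; a class absent from both prediction and
truth scores 1 (a correctly-empty prediction is not penalised — the
published convention is unstated, so this choice is explicit). Reported
overlap columns are foreground means, with the full per-class breakdown
retained. Aggregate standard errors use a seeded nonparametric bootstrap
of the mean (default 1000 replicates; 200 in the harness reports for
speed). Rank-sum significance testing between loss variants is available
from `stats::wilcox.test()` on the per-image columns and is deliberately
not re-implemented.

## Problem sizes used by the shipped checks

Unit and property tests run on grids between 4×4 and 64×64 (loop oracles
on 8×8×2 and 4×8×8×3); the finite-difference suite perturbs every entry
of 6×6×2 and 4×5×3 maps; the training-based check uses 200 images at
64×64 with a 10-epoch cap and three seeds. These sizes were chosen so the
full suite exercises every code path in well under half an hour on a
single CPU while leaving the training experiment enough capacity to show
its effect.

## Known limitations

* Geometric augmentation warps are 2-D; 3-D volumes get mirroring and
  brightness only (the 3-D pipeline in the source protocol is patch-based;
  `samplePatches()` provides the sampling grid).
* The tiny U-Net adapter handles single-channel 2-D inputs; other
  backends plug in through the adapter contract (`predict` / `step` /
  `lossOn`).
* Training at batch size 1 with learning rate 0.1 is faithful but
  fragile; a non-finite loss aborts with diagnostics rather than being
  silently clipped.
* Bootstrap confidence intervals treat images as exchangeable; there is
  no hierarchical structure (e.g. per-patient grouping).
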