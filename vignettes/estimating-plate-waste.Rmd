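---
title: "Estimating plate waste from before/after meal images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating plate waste from before/after meal images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospitals routinely record how much of a served meal a patient left on the
plate: plate waste tracks nutritional intake, flags malnutrition risk, and
feeds back into menu planning. The standard instrument is a Comstock-style
visual score — a trained observer rates the leftover on an ordinal 1–7
scale (1 = not consumed at all, 7 = zero remaining). It is quick but
subjective, and observers systematically disagree at intermediate levels.

`mealintake` implements the objective counterpart: given a photograph of
the tray **before** and **after** consumption, a convolutional network
regresses the *eaten fraction*

$$f = \frac{w_\mathrm{before} - w_\mathrm{after}}{w_\mathrm{before}} \in [0, 1],$$

where the $w$ are scale weights in grams, and simultaneously classifies
the food category. Ground truth for training comes from weighing the plate
on a digital scale before and after the meal.

## Model

Both images are encoded by one weight-tied convolutional backbone
(siamese; the two extractor branches of a late-fusion design share weights
here, which halves the parameter count without changing the interface) and
the two feature vectors are concatenated, before-first ("late fusion").
Five head wirings are provided over the fused vector $v \in
\mathbb{R}^{2F}$ ($2F = 4096$ at the published scale):

* **ST** — $v \to \mathrm{FC1} \to \mathrm{FC2} \to \hat f$: plain
  regression.
* **ST-GT** — $[v \oplus \mathbf{1}_c] \to \mathrm{FC1}^{+} \to
  \mathrm{FC2} \to \hat f$: the ground-truth category one-hot
  $\mathbf{1}_c$ is appended to the fusion (first layer input $4096 + 34$).
* **MT** — a shared FC1 trunk splits into a regression branch
  ($\mathrm{FC2} \to \hat f$) and a classification branch
  ($\mathrm{FC2}' \to \hat y_\mathrm{cat}$).
* **MT-IC** — as MT, but the classification branch's normalized score
  vector is concatenated into the regression branch's input before its own
  $\mathrm{FC1}^{+}$ (inter-task connection).
* **MT-GT** — as MT-IC with the ground-truth one-hot fed back instead of
  the prediction: an upper-bound reference with identical parameter
  shapes, so the two can be compared weight-for-weight.

The regression output passes through a logistic nonlinearity, so
$\hat f \in [0,1]$ for any weights. Training minimizes

$$L = \alpha\,\underbrace{|\hat f - f|}_{L_\mathrm{lo}} +
      (1-\alpha)\,\underbrace{\mathrm{BCE}(\hat y_\mathrm{cat},
      \mathbf{1}_c)}_{L_\mathrm{cat}}, \qquad \alpha = 0.9,$$

with the BCE averaged over categories; single-task models use
$L_\mathrm{lo}$ alone. Optimization is Adam with early stopping: training
halts after 20 consecutive epochs without validation improvement and the
best-validation weights are restored.

### Design choices in ambiguous corners

Several wiring details admit more than one reading; the package fixes them
as follows and exposes switches where reasonable:

* The printed decision-layer widths include an FC2 input of 1025 that no
  described connection produces, and a classification output of 50 against
  a 34-category catalog. The package uses FC2 input = `fc1_out` (1024) and
  emits `n_categories` scores (34 by default; set `n_categories = 50` for
  the literal head width, with the surplus read as reserved capacity).
* "Soft parameter sharing" is realized as the shared FC1 trunk with
  task-specific decision layers — the closest reading consistent with the
  drawn architecture.
* The MT-IC feedback is the softmax of the category logits by default
  (differentiable); a hard one-hot of the argmax is available via
  `category_feedback = "hard-indicator"`.
* The seven augmentations (horizontal/vertical flip, rotation ±15°,
  reflection padding up to 10%, Gaussian blur, sharpness, contrast) are
  mutually exclusive: exactly one is drawn per pair with probability 1/7
  and applied with identical parameters to both images, because the method
  compares before vs after appearance — independently transformed images
  would corrupt that signal. The stated per-transform probability of 1/7
  sums to 1 over seven transforms, which supports the exclusive reading;
  parameter ranges are not published and are fixed in the defaults above.
* Early stopping monitors the validation combined loss (validation MAE for
  single-task models) with a 1e-5 improvement threshold, and best weights
  are restored on stop — the monitored quantity and the restoration policy
  are not published; these are the standard choices.
* Weights are stored in grams as recorded; normalization to fractions
  happens only inside losses and metrics. Scales occasionally report
  `weight_after` marginally above `weight_before`; the default policy
  clamps the fraction to 0 with a warning because the loss presumes
  $f \in [0,1]$.

### Backbones

The published experiments fine-tune ImageNet-pretrained VGG-11/13/16/19
and ResNet-50/101/152 extractors. Pretrained weights cannot be bundled
with this package, so the named entries build *surrogate* stacks — stride-2
3×3 convolution stages of increasing capacity followed by global average
pooling and a learned projection to the standard 2048-wide feature
interface (fusion width 4096) — initialized randomly;
`pretrained = TRUE` requires an explicit weights file. The tested,
desk-scale path is the `tiny-test` backbone: three stride-2 conv stages
(8/16/32 channels), GAP, and a 64-wide projection at 64 px input. All
dimension contracts are identical across backbones, so head wiring
verified on `tiny-test` transfers unchanged.

## The synthetic scene generator

Real data of this kind — 524 annotated pairs over 34 hospital dishes —
requires a ward, a photo rig and a dietitian. The package therefore ships
a simulator that reproduces the *geometry* of the acquisition rig: a white
plate on a black/white checkerboard placemat with 2×2 cm squares, carrying
a coloured food region. For a pair with eaten fraction $f$ the after-image
region is the before-image region shrunk around its centroid by
$\sqrt{1-f}$, so the rendered area ratio is $1-f$ up to rasterization
error (verified to within 0.05 for $f \le 0.95$). Weight ground truth is
*defined* from rendered area (`density` grams/cm², default 1.3 — a
rice-like dish covering a 6 cm-radius region weighs ≈ 150 g), which makes
parameter recovery a closed-loop test: the quantity the network must
recover is exactly the quantity the generator encoded.

Categories differ by hue (golden-angle spacing) and shape (disk, ellipse,
blob cluster); portion size jitters ±15% around the category base, a
realistic serving variability. The simulated observer perceives the true
fraction plus Gaussian noise — SD 0.15 at mid-range fractions and 0.10
near empty/full plates, mirroring the published pattern of per-level
weight SDs (0.09–0.11 at the extreme levels vs 0.13–0.20 in between) —
and reports the nearest of the seven anchor levels $1/7, \dots, 1$. A
configurable fraction of after-images keeps a faint translucent oil film
over the food's footprint (opacity 0.15, a free parameter; the emulated
effect is only qualitative), reproducing the known failure mode where
appearance-based models see "leftover" on an oily but empty plate.

What the simulator does **not** emulate: perspective and camera pose,
shadows and specular highlights, utensils and garnish, texture families of
real dishes, and observer biases beyond symmetric noise. Passing the
recovery tests therefore demonstrates that the architectures, losses and
harness are wired correctly and that the networks can extract area- and
colour-based signal end-to-end — not that the published real-data error
levels transfer.

## Evaluation protocol

`make_folds()` partitions pairs into $k = 10$ near-equal blocks,
stratified by category; fold $i$ tests on block $i$, validates on the next
two blocks (cyclically) and trains on the remaining seven, realizing the
7/10 / 2/10 / 1/10 split exactly within one rotation, and the ten test
sets partition the dataset. Blocks carrying the $n \bmod k$ surplus
records are spread evenly around the cycle so that every fold's three set
sizes stay within one record of the ratios (for $n = 524$: test 52–53,
validation 104–105, train 366–367).

Reported metrics follow the published table shape: MAE (mean ± SD over
folds), classification accuracy (mean ± SD over folds), and class-wise MAE
pooled over the concatenated test folds — pooling because rare categories
(down to a single pair) can be absent from individual folds. The human
baseline maps the observer level $\ell$ to $\ell/7$ on the eaten-fraction
scale and takes the MAE against the scale-derived fraction. On the real
survey this baseline is 0.0926; the published networks reach ≈ 0.08 with
ResNet-101, and reproducing those absolute numbers requires the real
dataset and pretrained backbones, both outside this package's scope.

## Grad-CAM

Saliency maps weight the channels of the last convolutional activation of
the chosen image's backbone path (configurable; the published work does
not name the layer) by the spatial mean of the gradient of the target
scalar — the regression output, or one category's score — then rectify,
upsample to input size, and max-normalize. The target layer sits before
global pooling, so the map retains the full spatial grid. Before and
after images get separate maps. A map whose rectified response is
identically zero is returned as all zeros with `all_zero = TRUE` rather
than normalized — the signature of "no features extracted", which real
oily-plate failures produce. The map is invariant to positive scaling of
the target, and the gradient seed is placed on the pre-sigmoid regression
output so the bounding nonlinearity cannot shrink it.

## Numerical and problem-size choices

* Convolutions run as im2col + BLAS GEMM in compiled code; gradients of
  every layer are verified against central finite differences in the test
  suite (agreement ~1e-10).
* Category ties in `predict_category()` break toward the lowest food id.
* BCE scores are clamped to $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-7}$.
* The desk-scale recovery experiment trains the `tiny-test` backbone on 8
  categories × 50 pairs at 64 px (fold 1 of the 10-fold plan: 280 train /
  80 validation / 40 test), Adam at 1e-3 — the stock from-scratch rate;
  the package default of 1e-4 matches the published fine-tuning setting
  for pretrained backbones — for at most 150 epochs with patience 20 and
  augmentation off. On one CPU core this takes a few minutes per
  architecture, and the trained multi-task models reach test MAE well
  under 0.15 with classification accuracy above 0.85 against a 0.125
  chance rate; the exact numbers are computed, not quoted, by the test
  suite.
* `generate_dataset()` is bitwise deterministic given its seed, including
  the PNG bytes.

## Limitations

The surrogate backbones are not the pretrained extractors whose transfer
power drives the published real-data accuracy; results on real
photographs with this package would require supplying pretrained weights.
The simulator's idealized scenes make the recovery task easier than
hospital imagery — its role is correctness verification and protocol
rehearsal, not benchmark substitution. Training is single-threaded CPU
code built for small problems; at the published scale (seven deep
backbones × five architectures × 10 folds) a GPU framework would be the
right tool.
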