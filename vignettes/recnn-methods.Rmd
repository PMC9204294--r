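---
title: "Methods: the reparameterized CNN classifier and its phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the reparameterized CNN classifier and its phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `recnn()`, the choices
made where the design was genuinely open, what the phantom simulator
does and does not emulate, and the problem sizes the test suite runs at.

## The model

A sample is a pair (patch, metrics): an intensity patch cropped from an
MNI152-registered T1 volume, and a short vector of morphological
metrics (by default the three global tissue volumes GM, WM, CSF).
Preprocessing standardizes each volume to zero mean, unit SD over all
voxels and clips to $[-1, 2.5]$; the asymmetric range keeps bright
tissue while flooring background, and is meaningful only after
standardization, which is why clipping follows the z-score.
Normalization statistics are per volume — the only scope that requires
no cohort pass and therefore behaves identically at train and test
time.

The backbone is five blocks of 3×3×3 convolution (stride 1, zero
padding preserving extent), per-channel batch normalization, ReLU and
2×2×2 stride-2 max pooling in ceil mode (odd extents padded on the high
side). Ceil mode is the convention that maps the $[80,100,80]$ patch
through $80 \to 40 \to 20 \to 10 \to 5 \to 3$ and $100 \to \dots \to 4$
to the advertised 128 maps of $[3,4,3]$; floor-mode pooling cannot
reproduce that contract, and neither can any block count other than
five. The channel progression 8–16–32–64–128 fixes only its last value
by the 128-map contract; the rest follows the patch-CNN convention of
halving spatial extent while doubling width, and is configurable in
`recnn_arch()`.

The receptive-field calculator iterates
$l_k = l_{k-1} + (f_k - 1)\prod_{i<k} s_i$ from $l_0 = 1$ over any
flattened layer list. Over the pooling stack alone (five kernel-2,
stride-2 layers) it gives 32 — the reading under which each deep voxel
summarizes a 32×32×32 input region. Including the kernel-3
convolutions gives a strictly larger field; `arch_layers()` produces
both layer lists and the test suite pins the pooling-stack reading.

The bottleneck maps the flattened feature vector $h$ (length 4608 for
the default backbone) through two affine heads: $\mu = f_m(h)$ and
$\log\sigma^2 = f_s(h)$. Parameterizing the log-variance makes
$\sigma = e^{f_s(h)/2}$ positive by construction. Latent features are
sampled as $Z = \mu + \epsilon \odot \sigma$ with
$\epsilon \sim N(0,1)$ — the reparameterization that keeps sampling
differentiable. At inference the package uses $Z = \mu$ so that
evaluation is deterministic; sampled inference is available via
`recnn_control(sampled_inference = TRUE)`.

The objective is $l = l_{ce} + \alpha\, l_{kl}$ with
$l_{kl} = \tfrac12 \sum_j (\mu_j^2 + \sigma_j^2 - 1 - \log\sigma_j^2)$,
the closed form of the divergence from $N(0,1)$. Per batch, the
per-sample KL sums are reduced by their **mean**, not their sum — the
choice keeps the meaning of $\alpha$ independent of batch size.
Cross-entropy is computed from softmax probabilities with a $10^{-12}$
floor inside the logarithm: a confidently wrong prediction costs a
large finite value, never NaN, and the floor is unreachable at desk
scale.

Sampled latent features are concatenated with the metric vector — in
that fixed order — and classified by an MLP (default hidden sizes 64
and 32, ReLU, softmax output). Metrics are z-scored with training-split
statistics before concatenation because raw volumes (mm³) and latent
features live on incompatible scales. With `latent_dim = 0` the image
branch is bypassed entirely and the model degenerates to the
metrics-only MLP; with `alpha = 0` it is the conventional CNN arm.

## Training protocol

Defaults in `recnn_control()` follow the published recipe: Adam at base
rate 5e-4, batch 32, 120 epochs; the learning rate ramps linearly from
0 over the first two epochs *per optimizer step* (not per-epoch jumps),
plateaus, and is divided by 5 once per 40 epochs — i.e. at epochs 40
and 80 within a 120-epoch run; whether a decay would also fire at epoch
120 is moot at these defaults. "Shrinks 5 times per 40 epochs" is read
as division by 5, the only reading compatible with a
warm-up-then-plateau schedule. Splits are stratified by class with
per-class floor rounding (766 samples at 80% give 612/154, matching the
clinical cohort arithmetic); the protocol text says only "randomly
divided", but stratification stabilizes small-validation metrics.
Class imbalance is handled by drawing each epoch's sample order with
replacement, weighted by inverse class frequency, so the expected drawn
class ratio is 1:1. Validation metrics are reported at the final epoch
(`fit$history` retains every epoch, so best-epoch reporting is a
one-liner for the user).

All randomness — weight initialization, epoch shuffling/oversampling,
and the $\epsilon$ draws — derives from the master seed through
independent saved RNG substreams, so a fit is reproducible to the bit
and e.g. changing the number of epochs does not perturb the data
shuffle of earlier epochs.

## Numerical choices

* Batch norm uses batch statistics in training and running statistics
  (momentum 0.1, unbiased variance, $\varepsilon = 10^{-5}$) at
  inference.
* Backbone convolutions use He-normal initialization; MLP layers the
  $U(\pm 1/\sqrt{\text{fan-in}})$ convention of mainstream deep
  learning frameworks; the variational heads $f_m, f_s$ a small normal
  (SD 0.01) so latent distributions start near $N(0,1)$ and the KL term
  starts near 0 rather than exploding.
* Decision threshold ties (score exactly 0.5) predict positive, making
  confusion counts bit-reproducible; AUC is the normalized rank
  statistic with midranks, exact under ties, and agrees with a
  brute-force pair count to $10^{-9}$ in the tests.
* Degenerate inputs fail loudly: constant-intensity volumes (zero SD),
  crops beyond bounds (naming the offending axis), single-class label
  vectors, and non-finite training losses all raise errors rather than
  propagating silently. One-sided evaluation leaves SE or SP as `NA`,
  never 0.

## The phantom simulator

`phantom_config()` / `phantom_cohort()` emulate exactly the statistical
structure the classifier assumes: additive Gaussian background noise;
a small number of bright class-*independent* ellipsoids at random
positions (the redundant structure a CNN happily encodes); two bright
"hippocampus" ellipsoids at fixed mirror positions whose radius shrinks
by `atrophy_fraction` in the AD class (the localized volumetric
signal); and metric vectors drawn $N(\text{label} \times
\text{morph\_effect},\, 1)$, matching the z-scored-feature convention of
the classifier. Blob radii scale with the grid so that reduced-shape
phantoms keep the same geometry proportions. Each sample's substream
is derived from `(seed, label, index)`, so cohorts are
order-independent and any sample can be regenerated in isolation.

Defaults are one fixed set of study conditions: NC blob radius 8 voxels
(at the 80-voxel reference grid), atrophy fraction 0.3, unit noise SD,
four redundant blobs, three metrics with a 1.5 SD class shift, 100
samples per class. These mirror a clearly-separable clinical contrast;
the simulator does **not** model scanner physics, bias fields,
registration error, partial-volume effects, anatomical shape, or
multi-site distribution shift. Passing phantom tests therefore
demonstrates that the pipeline recovers a planted signal of the assumed
form and that the KL constraint behaves as designed — not that the
model attains any particular clinical accuracy.

## Problem sizes in the test suite

The behavioral tests train real fits at reduced sizes, chosen once as
the package's validation conditions: the constraint-trend and
signal-recovery experiments use 200-sample cohorts of 32×40×32 phantoms
with a 4–8–16–32–32 backbone, $J = 16$, 12 epochs (the step-decay
epochs are never reached at that length); the null-signal control sets
atrophy and metric shift to zero. The weight-sparsification experiment
needs the full 120-epoch schedule to accumulate optimizer steps, so it
runs on 16×20×16 phantoms with a 4–8–16–16–16 backbone; it measures the
fraction of latent features whose first-layer profile (maximum absolute
incoming weight) falls below 0.05, comparing $\alpha = 10$ against
$\alpha = 0$ over matched seeds at $J = 512$. The large-$J$ setting is
deliberate: the first-layer initialization scale $1/\sqrt{J + M}$ then
sits at the profile threshold, so the contrast
between discriminative features (whose weights grow under $\alpha = 0$
when latents carry signal) and KL-collapsed features (whose weights
stay near initialization under $\alpha = 10$) is visible within a short
training budget; at small $J$ the initialization scale alone exceeds
the threshold in both arms and the comparison is uninformative.

## Known limitations

* The engine implements exactly the published architecture family —
  kernel-3 stride-1 "same" convolutions and kernel-2 stride-2 ceil-mode
  pooling. Other kernel geometries are rejected at construction.
* Training is CPU-only and single-threaded beyond BLAS; full-scale
  80×100×80 cohorts train slowly compared to GPU frameworks. The
  default configuration is faithful, but phantom validation runs at
  reduced sizes.
* The hippocampal crop corner for clinical MNI-grid volumes ships as a
  config default (`inst/extdata/default_config.yaml`, corner
  `[50, 58, 50]`) centred on the template's hippocampal region; it is a
  configuration value, not a claim derived from data, and should be
  checked against the registration of any real cohort.
* Morphological metric dimension defaults to 3 (global GM/WM/CSF);
  regional-atlas variants are supported simply by longer metric vectors
  in the cohort table.
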