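# recnn

Reparameterized 3D convolutional networks for discriminating Alzheimer's
disease (AD) from normal controls (NC) on structural MRI.

## The problem and the model

Hippocampal atrophy is an early, visible signature of AD on T1-weighted
MRI, and both region-level morphometry (tissue volumes) and deep
convolutional features can detect it — but convolutional feature vectors
are large, redundant and highly correlated, which hurts classifiers
trained on small clinical cohorts. `recnn` implements a classifier that
*constrains* the deep features through a variational bottleneck before
using them:

1. **Backbone.** An `[80, 100, 80]` patch covering both hippocampi
   (cropped from an MNI152-registered volume, intensities standardized
   per volume and clipped to `[-1, 2.5]`) passes through five blocks of
   Conv3D (3×3×3, "same") → BatchNorm3D → ReLU → ceil-mode 2×2×2 max
   pooling, giving 128 feature maps of size `[3, 4, 3]` — a flattened
   deep feature vector *h* of length 4608. Each output voxel summarizes
   a 32×32×32 input region (the receptive field of the downsampling
   stack, `l_k = l_{k-1} + (f_k − 1)·∏ s_i`).
2. **Reparameterized bottleneck.** Two linear maps give a latent mean
   μ = f_m(h) and log-variance f_s(h) (σ = e^{f_s(h)/2}); latent
   features are sampled as **Z = μ + ε⊙σ**, ε ~ N(0, 1), so sampling
   stays differentiable.
3. **Objective.** l = l_ce + α·l_kl, where l_kl = ½ Σ_j (μ_j² + σ_j² − 1
   − log σ_j²) pulls every latent coordinate toward N(0, 1). Redundant
   coordinates collapse onto the prior and stop carrying information;
   discriminative ones survive. α trades the two terms.
4. **Classifier.** Z is concatenated with the morphological metric
   vector (gray-matter, white-matter, CSF volumes, z-scored on the
   training split) and classified by a small MLP with softmax output.

Training follows the published protocol: Adam (base rate 5e-4, batch
32), 120 epochs, a two-epoch linear warm-up from 0, rate divided by 5
every 40 epochs, stratified seeded 80/20 splits, inverse-frequency
oversampling of the minority class, and repeated cross-validation over
seeds. Evaluation reports ACC, SE, SP and rank-based AUC.

Because the clinical cohorts (ADNI, AIBL) are gated, the package ships
a 3D phantom simulator — `phantom_cohort()` — that plants the same
statistical structure: two bright "hippocampus" ellipsoids whose radius
shrinks in the AD class, class-independent redundant blobs, Gaussian
noise, and metric vectors with a class mean shift. Every stage of the
pipeline is testable offline against it.

## Worked example

```r
library(recnn)

# a 200-sample phantom cohort with a planted atrophy + metric signal
cfg <- phantom_config(shape = c(32, 40, 32), n_per_class = 100, seed = 0)
cohort <- phantom_cohort(cfg)

fit <- recnn(cohort, latent_dim = 16, alpha = 1,
             arch = recnn_arch(input_shape = c(32, 40, 32),
                               channels = c(4, 8, 16, 32, 32)),
             control = recnn_control(epochs = 12), seed = 0)
fit
#> Reparameterized CNN classifier (AD vs NC)
#> Call: recnn(samples = cohort, latent_dim = 16, alpha = 1, ...)
#>   latent dim J = 16, morph dim = 3, alpha = 1, seed = 0
#>   backbone: 4->8->16->32->32 channels on 32x40x32 patches
#>   validation (final epoch):
#>   n = 40  (TP 15, TN 18, FP 2, FN 5; threshold 0.50)
#>   ACC 0.8250  SE 0.7500  SP 0.9000  AUC 0.9075
```

The validation block is the held-out 20% of the cohort: of 40 held-out
phantoms the model classifies 33 correctly at threshold 0.5, and the
0.91 AUC is the probability that a random AD phantom outscores a random
NC phantom. `fit$history` holds per-epoch losses (ce, kl, total),
learning rate and validation metrics; `predict(fit, new_samples)`
returns class probabilities; `first_layer_weight_profile(fit)` exports
the per-feature first-layer weight magnitudes used to inspect latent
sparsification; `cross_validate(cohort, seeds = 0:4, ...)` repeats the
fit over seeds and reports mean ± SD per metric.

A command-line wrapper (`inst/cli/recnn`) exposes `simulate`, `train`,
`grid`, `eval` and `rf` subcommands driven by a YAML config
(`inst/extdata/default_config.yaml` carries the published defaults).

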