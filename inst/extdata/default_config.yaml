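# Default run configuration: the published protocol, ready to edit.

# Hippocampal patch crop on the MNI152 [181, 217, 181] grid.  The
# [80, 100, 80] box below is centered on the template's hippocampal
# region and covers both hippocampi; corner is 0-based.
crop:
  corner: [50, 58, 50]
  size: [80, 100, 80]

# Intensity clip range applied after per-volume standardization.
clip: [-1.0, 2.5]

arch:
  channels: [8, 16, 32, 64, 128]

train:
  lr_base: 0.0005
  batch_size: 32
  epochs: 120
  warmup_epochs: 2
  decay_every: 40
  decay_factor: 5
  train_fraction: 0.8
  alpha: 10
  latent_dim: 100
  hidden: [64, 32]
  seeds: [0, 1, 2, 3, 4]

simulate:
  shape: [80, 100, 80]
  n_per_class: 100
  signal_radius_nc: 8
  atrophy_fraction: 0.3
  noise_sd: 1.0
  n_redundant_blobs: 4
  morph_dim: 3
  morph_effect: 1.5
  seed: 0

grid:
  alphas: [0.1, 1, 10]
  latent_dims: [0, 16, 100]
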