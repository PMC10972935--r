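# ductseg

Anatomical-attention segmentation of the dilated pancreatic duct in 3D
abdominal CT.

A dilated main pancreatic duct — a thin dark tube inside the pancreas on
portal-venous CT — is a risk marker for pancreatic cancer, and an extreme
small-target segmentation problem: a few hundred foreground voxels against
tens of millions of background voxels. `ductseg` implements a coarse-to-fine
strategy against that imbalance:

1. **Pancreas localization.** A coarse pancreas mask (from a scalable V-Net
   family, or supplied as an oracle) defines a region of interest; volumes
   are clipped to [−200, 200] HU, min–max normalized to [0, 1], resampled to
   isotropic spacing (1 mm organ stage, 0.5 mm duct stage) and cropped to a
   fixed ROI window.
2. **Anatomical attention.** The mask gates every decoder level of the
   duct-stage FCN: coefficients
   𝒜ˡ = σ(conv₂ₓ₂ₓ₂(xˡ) + conv₁ₓ₁ₓ₁(pool(M))) ∈ [0, 1] multiply the skip
   features, x̂ˡ = 𝒜ˡ·xˡ, steering the network toward the whole organ
   anatomy instead of a learned (often too narrow) self-gating signal.
3. **Tubular-structure enhancement.** A Frangi vesselness channel
   F = (1 − e^(−Ra²/2α²)) · e^(−Rb²/2β²) · (1 − e^(−S²/2γ²)) for
   λ₂ ≤ 0, λ₃ ≤ 0 (else 0), computed from the scale-space Hessian with
   |λ₁| ≤ |λ₂| ≤ |λ₃|, α = β = 0.5 and γ = half the maximum Hessian norm,
   is masked to the pancreas, normalized, and fed as a second input channel.
   The dark duct is handled by intensity negation (`polarity = "dark"`).

The five network variants of the ablation ladder (`attention_unet`, `panet`,
`pamnet`, `mcpamnet`, `nmcpamnet`) are assembled from scalable V-Net / 3D
U-Net backbones (BN or IN), trained with Adam on the soft Dice loss through a
small reverse-mode autodiff engine built into the package (BLAS-backed
volumetric convolutions; no external deep-learning framework). Evaluation
reports DSC, sensitivity, NSD and HD95, spacing-aware. A deterministic
phantom generator (bright ellipsoidal organ + thin dark curved tube) makes
every stage testable without clinical data.

## Worked example

```r
library(ductseg)

# a synthetic case: bright organ ellipsoid, thin dark curved duct
ph <- generate_duct_phantom(phantom_config(seed = 1))
ph$volume
#> <volume> 64x64x64 voxels, spacing [0.5, 0.5, 0.5] mm, range [0.002357, 0.6363]
sum(ph$duct$data)                     # 438 duct voxels = 0.17% of the grid

# tubular-structure enhancement channel
enh <- postprocess_enhancement(
  frangi_filter(ph$volume, vesselness_params(), mask = ph$pancreas),
  ph$pancreas)
median(enh$data[ph$duct$data == 1])   # 0.403 inside the duct ...
median(enh$data[ph$pancreas$data == 1 & ph$duct$data == 0])  # ... 0.000 elsewhere

# pancreas ROI for the duct-stage network
roi <- crop_roi(ph$volume, ph$pancreas, target_size = 48, margin = 0)
dim(roi$roi$data)                     # 48 48 48, exactly invertible crop

# spacing-aware metrics: the duct mask shifted by one voxel against itself
shifted <- label_mask(array(c(ph$duct$data[-1], 0), dim(ph$duct$data)),
                      ph$duct$spacing)
metrics_report(shifted, ph$duct, spacing = ph$duct$spacing, case_id = "shifted-by-1")
#>        case_id      dsc sensitivity nsd hd95
#> 1 shifted-by-1 87.21461    87.21461 100  0.5
```

The one-voxel shift costs ~13 Dice points on a structure this thin (and
leaves a 0.5 mm HD95) — the scale sensitivity that makes duct segmentation
hard.

Training and the full cascade:

```r
cfg <- cascade_config(
  variant = "nmcpamnet",
  backbone = backbone_config("unet3d", levels = 3, initial_filters = 4,
                             norm = "IN", in_channels = 2),
  train = train_config(learning_rate = 3e-3, max_iterations = 120, seed = 11),
  roi_size = 48, margin = 4, clip = NULL)
model <- build_variant("nmcpamnet", cfg$backbone, seed = 42)
# ... train_model() on prepared ROI cases, then:
res <- run_cascade(ph$volume, cfg, model, pancreas = ph$pancreas, duct = ph$duct)
res$metrics
```

A command-line wrapper with `simulate`, `enhance`, `train`, `predict`,
`evaluate` and `run-experiment` subcommands ships in `inst/cli/ductseg.R`.

## Scope

The package reproduces the *method* — architectures, enhancement, attention,
training, metrics — at desk scale on synthetic data. The published clinical
accuracies on the private 30-case duct dataset (and the public pancreas
dataset training of stage 1) require data and GPU-scale compute that are
deliberately out of scope; see the methods vignette in `vignettes/` for the
full design rationale and limitations.
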