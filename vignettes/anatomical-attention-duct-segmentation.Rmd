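---
title: "Anatomical attention for dilated pancreatic duct segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical attention for dilated pancreatic duct segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ductseg)
```

## The problem

A dilated main pancreatic duct is a risk marker for pancreatic cancer. On
portal-venous abdominal CT it appears as a thin dark tube inside the pancreas:
a structure of a few hundred voxels in a volume of tens of millions, with poor
contrast against the surrounding parenchyma. Direct semantic segmentation of
such a target with a fully convolutional network (FCN) suffers from the
extreme foreground/background imbalance.

`ductseg` implements a coarse-to-fine strategy against this imbalance:

1. **Pancreas localization** — a coarse pancreas mask (from a scalable V-Net
   trained at 1 mm isotropic resolution, or supplied directly) restricts the
   problem to a region of interest (ROI) around the organ.
2. **Anatomical attention** — the same coarse mask gates every decoder level
   of the duct-stage FCN, steering the network's focus to the whole pancreas
   anatomy rather than letting it learn its own (often too narrow) gating
   signal.
3. **Tubular-structure enhancement** — a Frangi vesselness map of the ROI,
   masked to the pancreas and min–max normalized, enters the network as a
   second input channel so that tube-shaped intensity structure is available
   to the first convolution.

All stages are exercisable without clinical data through a synthetic phantom
generator (below).

## Preprocessing

CT intensities are clipped to $[-200, 200]$ HU and min–max rescaled to
$[0, 1]$. The bounds are fixed rather than per-volume so that intensities are
comparable across cases; $-200 \mapsto 0$, $0 \mapsto 0.5$, $200 \mapsto 1$
exactly. Volumes are resampled to isotropic spacing — 1 mm for the pancreas
stage, 0.5 mm for the duct stage — with trilinear interpolation for images
and nearest-neighbour lookup for masks (which preserves the binary label
set). The output shape per axis is `round(shape * spacing / target)`.

The pancreas ROI is the mask bounding box expanded by a margin (default 16
voxels), centered and zero-padded to a fixed window (default $160^3$; tests
and the desk-scale study use smaller divisible windows). Zero is the clip
floor, i.e. padded voxels look like the darkest soft tissue. The crop record
makes the operation exactly invertible, and the restored prediction is
guaranteed zero outside the window. When the expanded bounding box exceeds
the window, the window grows to cover it rather than resampling the ROI —
spatial resolution is never silently changed.

## Tubular-structure enhancement

The vesselness response is built from the scale-space Hessian: at scale
$\sigma$ (mm), second derivatives are computed by separable
Gaussian-derivative convolution (spacing-aware, replicate padding,
scale-normalized by $\sigma^2$). The sampled second-derivative kernel is
corrected to sum exactly to zero so constant volumes map to zero response.
Per voxel, the eigenvalues of the symmetric $3\times3$ Hessian are obtained
in closed form (the trigonometric solution for symmetric matrices, validated
against `eigen()` in the tests) and ordered by magnitude
$|\lambda_1|\le|\lambda_2|\le|\lambda_3|$. With

$$R_a = \frac{|\lambda_2|}{|\lambda_3|},\qquad
R_b = \frac{|\lambda_1|}{\sqrt{|\lambda_2\lambda_3|}},\qquad
S = \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2},$$

the response is

$$F = \left(1-e^{-R_a^2/2\alpha^2}\right)\,e^{-R_b^2/2\beta^2}\,
\left(1-e^{-S^2/2\gamma^2}\right)$$

when $\lambda_2 \le 0$ and $\lambda_3 \le 0$, and $0$ otherwise, with
$\alpha = \beta = 0.5$ and $\gamma$ recomputed per scale as half the maximum
Hessian Frobenius norm over the volume (restricted to the pancreas mask when
one is supplied). The multi-scale response is the voxelwise maximum over the
scale set.

Design choices where the formulation is genuinely open:

* **Polarity.** The sign condition above responds to *bright* tubes, but the
  duct is a *dark* line structure. The default `polarity = "dark"` negates
  intensities before differentiation, which flips the Hessian sign and makes
  the printed condition fire on the duct; `"bright"` is available for
  vessel-like targets. (Whether one negates the image or flips the sign
  condition is mathematically equivalent; we negate.)
* **Scale set.** Defaults $\sigma \in \{0.5, 1, 1.5, 2\}$ mm cover duct radii
  of roughly one to four voxels at the 0.5 mm working resolution.
* **$\gamma$'s reference region.** "Half the maximum Hessian norm" is read
  over the masked region when a mask is given, else the whole volume: the
  statistic should describe the structures actually being discriminated.
* **Degenerate eigenvalues.** $\lambda_3 = 0$ means no curvature, hence no
  tube: $R_a$ and $R_b$ are defined as 0 and the response is 0.
* **Ordering of operations.** The enhancement channel is computed on the
  resampled, cropped ROI (not on the full-resolution volume): it feeds the
  duct-stage network, so it is computed on that network's grid.

Post-processing zeroes the response outside the pancreas mask and min–max
rescales the surviving values into $[0, 1]$ (`normalize = FALSE` keeps the
raw masked response — the two variants fed to the two-channel networks).

## Network family

Two backbone families are provided, both fully convolutional encoder–decoders
with channels doubling per level.

* **V-Net convention**: $5^3$ convolutions, `min(level, 3)` convolutions per
  stage with a residual connection around each stage, $2^3$ stride-2
  down-convolutions doubling channels, $2^3$ transposed up-convolutions
  halving channels, and *additive* fusion of the encoder skip with the
  upsampled decoder feature. PReLU activations.
* **3D U-Net convention**: $3^3$ convolutions with channel doubling inside
  each level, $2^3$ max pooling, channel-preserving up-convolutions and
  concatenated skips. ReLU activations.

Either batch or instance normalization follows every convolution. These
internals were pinned by reproducing the published parameter counts of the
standard configurations — 19.1 M for the standard 3D U-Net, 41.2 M for the
standard five-level V-Net, 9.9 M for the four-level/16-filter V-Net, 166.2 M
and 664.7 M for the six-level variants — to within 0.05 M before rounding.
Notably, only the additive-skip decoder reproduces the V-Net numbers;
a concatenating decoder at these widths is roughly 65 M parameters. Counts
depend only on layer shapes, never on input size.

### Anatomical attention

At each decoder level $l$, the skip feature map $\mathbf{x}^l$ is gated by a
coefficient field $\mathcal{A}^l \in [0,1]$:
$\hat{\mathbf{x}}^l = \mathcal{A}^l \cdot \mathbf{x}^l$ (voxelwise, broadcast
over channels). The coefficients are produced by a $2^3$ stride-2
convolution of $\mathbf{x}^l$, summed with a $1^3$ convolution of the gating
signal at the same (half) resolution, passed through a sigmoid, and
trilinearly upsampled back to $\mathbf{x}^l$'s grid. The gating signal is

* the **pancreas mask**, adaptively average-pooled to the gate's resolution
  (anatomical attention), or
* the **next-coarser decoder feature** (self-gating, the attention-gated
  U-Net baseline).

Two points where the published description is under-determined, and the
choices made: the mask is pooled *per level* to the gated resolution (pooling
everything to the bottleneck size cannot match a stride-2-convolved shallow
level); and the gate uses a single-channel sigmoid with no intermediate
ReLU — the simplest form consistent with a coefficient field in $[0,1]$.
With all gate weights zero the coefficients are exactly $\sigma(0) = 0.5$;
saturating the gate reproduces the ungated forward — both are asserted in
the tests.

### Multi-scale aggregation

Instead of predicting only from the finest decoder level, each level
(including the bottleneck) is mapped by a $1^3$ convolution to class
channels, trilinearly upsampled to full resolution, concatenated and fused by
a final $1^3$ convolution. Only this fused output is trained (a single Dice
loss); per-level deep-supervision losses are deliberately not added, since
the aggregation is described as *similar to* deep supervision, not as
auxiliary supervision.

### The variant ladder

| variant | attention source | aggregation | enhancement channel |
|---|---|---|---|
| `attention_unet` | self-gating | – | – |
| `panet` | pancreas mask | – | – |
| `pamnet` | pancreas mask | yes | – |
| `mcpamnet` | pancreas mask | yes | raw (masked) |
| `nmcpamnet` | pancreas mask | yes | normalized |

`mcpamnet` vs `nmcpamnet` is interpreted as un-normalized vs min–max
normalized *masked* response: the contrast being tested is normalization,
so masking (which defines the channel's support) is kept in both.

## Training

Adam (learning rate $10^{-4}$ by default, $\beta_1 = 0.9$,
$\beta_2 = 0.999$) minimizes the soft Dice loss

$$L = 1 - \frac{2\sum_j p_j t_j + \varepsilon}{\sum_j p_j + \sum_j t_j + \varepsilon},
\qquad \varepsilon = 10^{-5},$$

with batch size 2 and no data augmentation. $\varepsilon$ and the
binarization threshold (0.5) are unstated in the source formulation; the
values above are the field's conventions. Cross-validation uses balanced
random folds (sizes differing by at most one), deterministic in the seed.
All training randomness — fold assignment, batch shuffling, weight
initialization (Kaiming-style) — derives from configuration seeds, so runs
are exactly reproducible.

The networks train through a small reverse-mode automatic differentiation
engine built into the package (tensors are `(x, y, z, batch, channel)`
arrays; convolutions are sums of per-kernel-offset BLAS contractions with the
gather/scatter loops in compiled code). Every operator's pullback is
validated against central finite differences in the test suite, and
whole-network gradients are spot-checked parameter by parameter. Batch
normalization keeps running statistics (momentum 0.1) for evaluation mode;
instance normalization is stateless.

## Evaluation metrics

Four spacing-aware measures, reported per case and as mean ± SD:

* **DSC** $= 200\,|A\cap B|/(|A|+|B|)$ (%); two empty masks agree perfectly.
* **Sensitivity** $= 100\,|P\cap G|/|G|$ (%); undefined for empty ground truth.
* **HD95** — the 95th percentile of the pooled symmetric surface-to-surface
  nearest distances, in mm.
* **NSD** — the fraction of surface voxels of each mask within a tolerance
  $\tau$ of the other surface (%), $\tau = 1$ mm by default.

Surfaces are foreground voxels with a 6-connected background neighbour
(volume borders count as background); distances are Euclidean between voxel
centers in world mm, computed exactly by (chunked) pairwise enumeration —
appropriate for thin structures whose surfaces are small. The surface
convention and $\tau$ are not fixed by the source formulation, so published
surface-metric values are not exactly recomputable even in principle; the
defaults here are stated so results are reproducible *within* the package.
Empty predictions yield DSC 0, sensitivity 0 and missing surface metrics
rather than fabricated values.

## The phantom generator

`generate_duct_phantom()` builds the geometry the method targets: a bright
ellipsoidal organ (default semi-axes $12 \times 9 \times 7$ mm, intensity
0.55) containing a thin dark tube (radius 1 mm, intensity 0.3) on a darker
background (0.1), with additive Gaussian noise ($\sigma = 0.02$) on a
$64^3$ grid at 0.5 mm isotropic spacing — values chosen so a normalized
portal-venous ROI is mimicked on the clip-normalized intensity scale. The
tube's centerline is a smooth spline through random control points confined
to the inner 65 % of the ellipsoid (a straight-tube mode exists for analytic
volume checks). The duct occupies well under 1 % of the grid and under 10 %
of the organ, reproducing the class imbalance that motivates the attention
strategy; the duct is strictly inside the organ and strictly darker than it,
which is what the dark-tube polarity of the enhancement channel relies on.

What the phantoms do *not* emulate: neighbouring organs and vessels (the
main source of false positives in real CT), intensity inhomogeneity,
partial-volume effects at anisotropic native spacing, and anatomical
variability of duct calibre. Passing the phantom studies therefore
demonstrates that the pipeline's machinery — preprocessing, enhancement,
attention wiring, optimization, restoration, evaluation — is correct and
recoverable at desk scale, not that the published clinical accuracy is
reproduced; that would require the private 30-case dataset and GPU-scale
training, which are out of scope.

## The desk-scale recovery study

The end-to-end check trains a tiny `nmcpamnet` (3-level 3D U-Net backbone,
4 initial filters, instance norm, $48^3$ ROI) on four phantoms (ellipsoid
semi-axes $10 \times 8 \times 6$ mm so the organ plus margin fits the
$48^3$ window) for 120 Adam steps at learning rate $3\times10^{-3}$ and
batch size 2, then evaluates through the full cascade with the oracle
pancreas mask. The elevated learning rate is deliberate for an overfitting
study of a 4-case training set; the package default remains $10^{-4}$.
Training Dice exceeds 90 % and the cascade reproduces the same per-case DSC
through the crop/restore path. On one CPU core the 120 steps take on the
order of ten minutes; problem sizes were chosen so the whole suite stays
desk-scale.

## Known limitations

* The stage-1 pancreas segmentation model is provided as machinery (any
  backbone can be trained and plugged in); the shipped studies use oracle
  masks, since the public pancreas dataset is not bundled.
* Exact Hausdorff/NSD values depend on the surface convention (stated above).
* Batch normalization statistics are computed over whatever batch layout the
  caller uses; with gradient-accumulation-style single-sample batches it
  degenerates toward instance normalization.
* The pairwise surface-distance computation is exact but quadratic in surface
  size; for organ-scale masks at sub-millimetre spacing a distance-transform
  implementation would be preferable.
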