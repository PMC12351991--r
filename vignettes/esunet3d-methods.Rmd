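---
title: "Methods: attention-enhanced full-scale 3D segmentation with region-specific scaling and dynamically weighted Dice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-enhanced full-scale 3D segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esunet3d)
```

## The problem

Delineating tumours in co-registered PET/CT volumes is a voxel-wise binary
classification problem with severe class imbalance: the lesion typically
occupies well under 5% of the volume, its boundary is irregular, and labelled
3D training data is scarce. This package implements a complete CPU-runnable
toolkit for that setting: the ES-UNet architecture family (a 3D U-Net with
full-scale, attention-gated skip connections and deep supervision), a
label-aware geometric augmentation called Region Specific Scaling (RSS), a
Dynamically Weighted Dice (DWD) loss that rebalances precision and recall on
the fly, volumetric overlap metrics, and a seeded phantom generator so every
component is exercisable end to end without external data.

## The network

The encoder has `N = 4` levels. Level 1 applies two (3×3×3 convolution →
batch norm → ReLU) units at full resolution; each deeper level first halves
all spatial dims with a stride-2 max pool and doubles the channel count, so
with base width `C_e` the deepest feature map has `8·C_e` channels at 1/8
resolution. Input channels are 2 (CT + PET) or 1 (single modality).

Every decoder level `j` receives `N` paths (in the full `"both"` variant):

* **Encoder level `i < j`** — channel attention, a max pool with kernel =
  stride = `2^(j−i)`, then a 3×3×3 convolution to the common path width `C`.
* **Encoder level `i = j`** — channel attention, two 3×3×3 convolutions and
  one 1×1×1 convolution to `C` channels.
* **Decoder level `i = j+1`** — a 2×2×2 transposed convolution with stride 2
  (bare: no norm or activation), then a 3×3×3 convolution to `C`.
* **Decoder level `i > j+1`** — trilinear up-sampling by `2^(i−j)`, then a
  3×3×3 convolution to `C`.

The concatenated paths (`N·C` channels) pass through one 3×3×3 convolution
whose output width is standardised to `N·C`. Channel attention
(squeeze-and-excitation with bottleneck ratio 0.25) sits on every
encoder-to-decoder path and on none of the decoder-to-decoder paths. Each
decoder level carries an auxiliary head — 1×1×1 convolution to one channel,
trilinear up-sampling by `2^(j−1)` to full resolution, sigmoid — and the
final prediction is the equally weighted mean of the head outputs. The
ablation variants `enc_only`, `dec_only` and `base` prune the path sets down
to, respectively, full-scale encoder paths only, full decoder paths only, and
the conventional same-level + adjacent wiring.

Because no deep-learning framework is available to (or desirable for) this
package, the 3D primitives (convolution via chunked im2col + GEMM,
transposed convolution, max pooling, trilinear resampling) are implemented in
C++ and composed through a small reverse-mode gradient tape in R. All
gradients are verified against naive reference implementations and central
finite differences in the test suite.

Implementation choices worth knowing:

* **Bias-free convolutions before batch norm.** The normalisation subtracts
  the per-channel mean, so a convolution bias there is exactly cancelled and
  its gradient is identically zero; none is allocated. Heads and transposed
  convolutions (not followed by a norm) keep their biases.
* **Per-sample batch statistics.** Training uses batch size 1, so batch norm
  reduces to per-channel statistics over the sample's voxels, and evaluation
  uses the same rule (deterministic, no running averages). At a degenerate
  1×1×1 bottleneck this makes the normalised output equal β; inputs of 16³
  and larger (the package's working range) keep at least 2³ voxels per level.
* **Attention bottleneck width** is `round(0.25·C)` with a floor of 1, and
  its bias starts at 1 so a width-1 gate cannot be born ReLU-dead.
* **Initialisation** is fan-in-scaled Gaussian with an optional seed;
  binarisation thresholds the fused map at 0.5 with ties going to foreground.

## The DWD loss

With voxel labels `y_i ∈ {0,1}` and predicted probabilities `p_i`, the soft
precision and recall coefficients are

    C_P = Σ y_i p_i / Σ p_i²,    C_R = Σ y_i p_i / Σ y_i²,

and the dynamic weights are `w_P = 1 − (C_P − C_R)`, `w_R = 1 − (C_R − C_P)`
(so `w_P + w_R = 2`, and both are 1 when the coefficients agree). The loss is

    L_DWD = 1 − 2 Σ y_i p_i / (w_R Σ y_i² + w_P Σ p_i² + ε).

Two subtleties:

* **Weight pairing.** Printed sources of this loss family disagree with
  their own narrative about which sum each weight multiplies. Only the
  pairing above — `w_P` on the prediction mass `Σp²` — makes `w_P > 1`
  penalise false positives more strongly and magnifies the loss under
  precision/recall disparity (the denominator shrinks by
  `(C_R−C_P)²·Σyp / (C_P·C_R) ≥ 0` relative to plain Dice). The package
  defaults to this `"narrative"` pairing and keeps the opposite
  `"as_printed"` pairing selectable; a test documents that the printed
  pairing *shrinks* the loss under disparity.
* **Weight clipping.** With soft predictions the coefficients can exceed 1
  (`y = 1, p = 0.5` gives `C_P = 2`), making a raw weight negative and the
  loss unbounded. Weights are clipped to `[0, 2]`, which leaves the
  degenerate-to-Dice behaviour near equality untouched.

The training objective is `mean focal + α·DWD` with focal focusing
parameter `γ = 2` (admissible range `[0, 5]`) and `α = 1`; `ε = 1e-6`
smooths every ratio. The gradient treats the dynamic weights as constants of
the current prediction — they describe the present precision/recall state
rather than being differentiated through — which also keeps the gradient
bounded where clipping is active. Two empty masks conventionally score 0
loss. Multi-class extensions are out of scope.

## Region Specific Scaling

RSS rescales only the slab of the volume that spans the labelled region.
Per axis: take the global min/max indices of all nonzero label voxels
(disjoint lesions contribute jointly), rescale that slab — all image
channels trilinearly, the label nearest-neighbour — by a ratio `r`, reattach
the outer slabs unscaled, and restore the original extent: for `r < 1` the
assembly is centred and mirror-padded at both ends (reflection without
repeating the edge voxel; odd remainder to the low-index end), for `r > 1`
the excess is cropped symmetrically (odd remainder from the high-index end).
The defaults are `r ∈ [2/3, 3/2]` drawn uniformly in a single draw; a config
flag switches to a fair coin between `[r1, 1]` and `[1, r2]`, since the
source material fixes only the range, not the distribution. Axes are visited
in the fixed order depth → height → width, each selected independently with
probability `p = 1 − (1 − p_RSS)^(1/3) ≈ 0.2063` so that at least one axis
is transformed with probability 0.5; bounds are recomputed before each
axis's transform (sequential semantics). The RNG draw order (one uniform per
axis selection, one more per selected axis) is fixed so seeded runs replay.

Mirror/rotation augmentation precedes RSS: with probability 0.5 a flip along
one uniformly chosen spatial axis, then rotations about the three axes by
angles drawn from Uniform(−15°, 15°), composed into a single trilinear
(nearest for the label) resampling pass about the volume centre to avoid
interpolating three times. Out-of-volume voxels are filled with 0. Whether
the source protocol meant one in-plane rotation or three axis-wise ones is
ambiguous; three axis-wise rotations in fixed order were chosen.

## Training pipeline

Cases are split by shuffling with a seed and holding out
`floor(0.2·n)` for validation — the only rule consistent with the published
splits 224→(180, 44), 20→(16, 4) and 41→(33, 8). Optimisation is Adam
(β₁ = 0.9, β₂ = 0.99, ε = 1e-8, no weight decay) under cosine annealing with
warm restarts: `lr = lr_min + ½(lr_max − lr_min)(1 + cos(π t / T))` with
`t = epoch mod T`, `lr_max = 1e-3`, `lr_min = 1e-5`, `T = 25` epochs. Every
deep-supervision head receives the full objective and the head losses are
averaged — mirroring the equal-weight prediction fusion, since the loss
aggregation is otherwise unspecified. Batch size defaults to 1. Evaluation
always runs whole volumes (no patches, no test-time augmentation) and
reports DSC, IoU and VOE per case plus the mean over cases (mean-over-cases,
not pooled-over-voxels, is the implemented aggregate). Validation DSC is
computed on the fused output; the best-validation-DSC parameters are kept as
the checkpoint. All randomness (init, shuffling, augmentation) derives from
the config seed.

## The phantom generator

`make_phantom()` emulates the statistical shape of a co-registered PET/CT
case: a structure channel with three intensity plateaus (ambient 0, body
0.35, inner organ 0.7, arbitrary normalised units) plus Gaussian noise
(sd 0.05); an uptake channel with background 0.1 and a smooth lesion signal
that peaks at `uptake_contrast` (default 3) in the centre and is half that at
the lesion surface, plus noise. The lesion is an ellipsoid with semi-axes
drawn from [6, 10] voxels (in a 64³ volume — about 0.3–1.6% of the voxels,
inside the 0.1–5% imbalance band), radially perturbed by a bounded low-order
polynomial in the direction cosines (amplitude 0.15 of the radius by
default), which keeps the region star-shaped about its centre and hence
6-connected. Each case derives its own RNG stream from (seed, case index),
and identical specs reproduce bit-identical volumes.

What the phantoms deliberately do not model: Hounsfield-calibrated CT,
PET kinetics or SUV scaling, inter-modality misregistration, and anatomy
beyond nested ellipsoids. Tests passing on phantoms therefore demonstrate
the correctness of the machinery (shapes, gradients, invariances,
optimisation) and the feasibility of fitting — not clinical segmentation
accuracy on real PET/CT.

## Numerical choices and degenerate inputs

* Resampling uses the half-pixel-centre convention; a same-shape resize is
  bit-exact, and nearest-neighbour label resampling keeps masks binary.
* An all-zero label makes RSS a no-op (with a notice); two empty masks score
  DSC = IoU = 1, VOE = 0, flagged as `both_empty`.
* A constant-valued channel z-scores to all zeros rather than dividing by
  zero.
* Spatial dims must divide by `2^(N−1)`; the error names the divisor.
* The losses are finite for all `p ∈ [0,1]` (including exact 0/1) through
  `ε`-smoothing of logs and ratios.

## Problem sizes used in the checks

The test-suite and acceptance-script runs use deliberately small instances
chosen as the package's own working scale: 16³–48³ phantoms for augmentation
and IO properties, one 64³ forward pass at full width (base 32) for the
encoder schedule, 10,000 seeded draws for the RSS frequency calibration, and
a base-8/path-8 network overfitting one 32³ phantom (200-step budget) as the
memorization capacity probe. Training-scale benchmark results on external
datasets (HECKTOR, MSD) are out of scope: they require the original data and
GPU-scale optimisation, and nothing in this package claims those numbers.

## Known limitations

* Single foreground class only; the dynamic weighting needs extra design for
  multi-class use.
* CPU-only double-precision execution: suitable for toy and moderate sizes,
  not for full-resolution training runs.
* Batch norm with per-sample statistics departs from frameworks that keep
  running averages; checkpoints are self-contained but not numerically
  comparable to framework-trained weights.
* DICOM ingestion, SUV computation and registration are out of scope; inputs
  are assumed co-registered NIfTI.
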