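---
title: "HACR-Net: model, degradation protocol, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HACR-Net: model, degradation protocol, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-resolution structural MRI is expensive to acquire: resolution trades off
against scan time and motion artifacts. Single-image super-resolution (SR)
reconstructs a high-resolution (HR) slice from a low-resolution (LR)
observation. `hacrnet` implements a hybrid-attention channel-retention
convolutional network for this task, together with everything needed to train
and evaluate it end-to-end on one CPU: the LR degradation operator, an L1/Adam
training loop, PSNR/SSIM metrics, and a synthetic phantom generator that
stands in for real brain MRI at desk scale.

Because no deep-learning framework is a dependency, the package carries its
own convolution engine: stride-1 same-padded 2D convolution implemented as
shift-and-GEMM over kernel offsets (one BLAS `dgemm` per tap into a padded
channels-last buffer), with exact hand-derived reverse-mode gradients for
every primitive (convolution, PReLU, sigmoid gating, global average pooling,
channel/spatial masks, channel concatenation, sub-pixel shuffle). Gradient
correctness is pinned by central finite-difference tests.

## Architecture

For an LR input $I_{LR} \in [0,1]^{1 \times H \times W}$ the network computes

1. **Shallow hybrid attention (HAM).** $F = \mathrm{PReLU}(\mathrm{Conv}_{3\times3}(I_{LR}))$
   is gated twice: a channel mask
   $\sigma(\mathrm{Conv}_{1\times1}(\mathrm{PReLU}(\mathrm{Conv}_{1\times1}(\mathrm{GAP}(F)))))$
   (squeeze ratio $C/\rho$), then a spatial mask
   $\sigma(\mathrm{Conv}_{1\times1}(\mathrm{PReLU}(\mathrm{Conv}_{7\times7}(\mathrm{Conv}_{1\times1}(F')))))$
   broadcast over channels. The 7×7 kernel gives the spatial gate a wide
   receptive field, matching the scale of anatomical boundaries. The gated
   features $F_1$ also feed the global skip connection.
2. **N context-aware aggregation modules (CAAM).** Each module applies a
   pre-activated residual block, a shared 3×3 convolution producing $c_{in}$,
   and two parallel branches:
   - **MFAB** (multiscale aggregation): two branches
     $\mathrm{Conv}_{3\times3}(\phi(\mathrm{Conv}_{3\times3}(\phi(c_{in}))))$ and
     $\mathrm{Conv}_{1\times1}(\phi(\mathrm{Conv}_{3\times3}(\phi(c_{in}))))$ are summed,
     re-weighted by a squeeze-style attention over their pooled descriptor,
     and added to a 1×1 high-frequency path.
   - **CRAB** (channel retention): a 3×3 convolution $h$, whose pooled
     descriptor passes through a *wide* 1×1 bottleneck
     ($C \to C_w \to C_w \to C_w \to C$ with a single PReLU) and a sigmoid to
     gate $h$; the gated map is added back to $h$. The contract $C_w \ge C/2$
     keeps the bottleneck far wider than the classical squeeze-excitation
     $C/16$, which is the block's design point: channel re-weighting without
     aggressive compression of descriptor information.
   The branch outputs are concatenated (2C), fused by a 1×1 projection back
   to C, and added to the module input. Zeroing the fusion projection makes
   the module an exact identity — a property the test suite asserts for every
   module index.
3. **Reconstruction.** A 3×3 convolution plus the global skip, then sub-pixel
   (PixelShuffle) upsampling: one $C \to 4C$ conv + shuffle stage for ×2, two
   cascaded stages for ×4 (a single $C \to 16C$ stage is available behind
   `upsample_single_stage`, but the cascade is the default since the near-equal
   published parameter budgets for ×2 and ×4 weakly support it), and a final
   3×3 convolution to one channel.

All convolutions are stride 1 with same-size zero padding and biases; every
activation is a PReLU with per-channel learnable slopes (initial slope 0.25).
Each activation occurrence is its own parameter tensor (no slope sharing).

### Where the printed architecture is ambiguous

Two places in the source description disagree with themselves; the package
follows the more granular algorithmic listing in both cases and keeps the
choices documented here:

- *Spatial attention depth*: the prose formula has three convolutions
  (1×1 reduce, 7×7, 1×1 to one channel); the pseudocode shows only two. The
  three-convolution form is implemented, with the intermediate width
  $C/\rho_s$ configurable.
- *CRAB residual*: the pseudocode adds the un-gated spatial features $h$;
  the displayed equation adds the block input instead. The pseudocode form
  ($h \otimes \mathrm{mask} + h$) is implemented.
- *MFAB activation placement*: the pseudocode pre-activates $c_{in}$ inside
  each branch; the displayed equations post-activate. The pseudocode is
  followed uniformly, and the high-frequency 1×1 path carries no activation,
  again per the pseudocode.

## Calibrating the unpublished widths

The architecture's published constants are the module count (10), the scale
factors (2, 4) and a total budget of 1,674k trainable parameters. The channel
width $C$, attention ratios $\rho, \rho_s$ and retained width $C_w$ are not
published. `calibrate_config()` therefore enumerates a candidate grid and
returns the configuration whose exact parameter count is nearest the budget
(ties toward smaller $C$, then smaller $C_w$).

With the faithful layer enumeration (seven 3×3 convolutions per module plus
the 1×1 projections, biases and PReLU slopes), the count is approximately
$(67.5 + 2/\rho)\,N\,C^2$ plus ~$45 C^2$ for the head and reconstruction, so
integer steps of $C$ move the total by tens of thousands of parameters and
$C_w$ provides the fine adjustment (~$2N(C + 2C_w)$ per unit). The default
grid is $C \in 40..56$, $\rho, \rho_s$ any divisor of $C$ in $2..16$, and
$C_w \in [C/2, 2C]$ — widths above $C$ are deliberately admitted, since
*retention* (not compression) is the block's stated intent. The winner,

```
C = 45, rho = 9, rho_s = 5, Cw = 81  ->  1,673,977 parameters (1,674k)
```

is frozen as `hacr_reference_config()`. `count_parameters()` is verified in
the tests against an independent closed-form enumeration over a grid of
twelve-plus configurations, and the acceptance suite re-runs the calibration
from scratch.

## Degradation protocol

LR observations are synthesized from HR slices by a 3×3 Gaussian blur with
$\sigma = 1$ followed by bicubic decimation (×2 or ×4), after per-volume
min–max normalization to $[0,1]$; normalization precedes degradation. Choices
the protocol leaves open, fixed as package defaults:

- **Bicubic dialect** $a = -0.5$ (Catmull–Rom), configurable; sampling is
  center-aligned with edge clamping and *no* anti-aliasing prefilter — the
  protocol's explicit blur is the only low-pass step. Published bicubic
  baselines are dialect-sensitive, so absolute comparisons to them are not
  asserted anywhere.
- **Blur border**: mirror-without-edge-duplication reflection, avoiding dark
  rims at the skull/background boundary.
- **Normalization granularity**: per volume, preserving inter-slice contrast.

The operator preserves constants to within 1e-6 (asserted), clamps to
$[0,1]$, and is bit-deterministic.

## Training

The published recipe is implemented exactly for the `"paper"` profile: Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$), learning rate
$10^{-4}$, constant (no schedule, no weight decay, no clipping, no
augmentation), batch 32, 250 epochs, L1 objective. Model selection is by
best validation PSNR (the selection metric is unstated; mean PSNR is the
field's default).

The `"desk"` profile is the package's CPU-feasible counterpart used by the
tests and the acceptance script: width 16, 4 modules, ×2, 64×64 phantoms,
batch 8, learning rate $10^{-3}$, 24 epochs over 200 pairs (600 optimizer
steps). These sizes were chosen so the full loop (data synthesis, training,
held-out evaluation) completes in minutes on a single CPU while leaving a
comfortable margin over the bicubic baseline; the learning-capability test
asserts a ≥ 0.5 dB held-out PSNR margin, a conservative floor that is an
artifact property, not a published number.

**Initialization** (unpublished): Kaiming fan-in normal with the PReLU gain,
seeded, with the fusion projections and the final output convolution
downscaled by 0.1. This "near-identity" start leaves every aggregation module
close to (but not exactly) the identity and the initial prediction small, so
the shallow path learns interpolation first and the deep modules specialize
gradually. In desk-scale experiments this init converges several times faster
than the plain Kaiming start without changing the architecture; all
parameters remain nonzero and receive gradient from the first step (asserted
by the gradient-completeness test).

`train_control(lr_decay =)` optionally applies a geometric per-epoch decay
(default 1, i.e. the published constant rate). It exists because Adam at a
constant rate stalls at a rate-dependent loss floor; the single-pair overfit
sanity check (drive L1 below $10^{-3}$) uses `lr = 2e-3, lr_decay = 0.998`.

## Metrics

- **PSNR**: $10\log_{10}(L^2/\mathrm{MSE})$ with $L = 1$ for $[0,1]$ images
  (the 8-bit $(2^n-1)^2$ form is identical after rescaling). Identical pairs
  report an `Inf` sentinel, excluded from aggregates with a logged count.
- **SSIM**: canonical windowed form (11×11 Gaussian window, $\sigma = 1.5$,
  $k_1 = 0.01$, $k_2 = 0.03$, population moments, windows fully inside the
  image, full slice, no border crop). The printed equation in the source
  description garbles the standard form (duplicated denominator, missing
  $\mu^2$ terms, $\sigma_x\sigma_y$ where the covariance belongs); since the
  surrounding text defines the cross-covariance, the canonical form is
  implemented. The test suite pins the implementation to a frozen value from
  an independent reference implementation on a seeded 64×64 pair (1e-6) and
  to the constant-image closed form $(2ab + C_1)/(a^2 + b^2 + C_1)$.
- **LPIPS**: exposed only as a plugin interface (`lpips(x, y, backend)`)
  computing the feature-weighted distance over caller-supplied pretrained
  features; no weights ship with the package, absent backends raise an error
  and the metric is reported as absent, never zero. Numeric agreement with
  published LPIPS values is out of scope.

## The phantom generator

`generate_phantom()` emulates what matters for SR at desk scale: overlapping
soft-edged ellipses with well-separated mean intensities (piecewise-smooth
"tissue" classes over a dark background, giving a multi-modal histogram),
band-limited texture (blurred white noise, default SD 0.02), a smooth
multiplicative bias field (low-order polynomial, default ±8%), and Gaussian
pixel noise (default SD 0.01), clipped to $[0,1]$. Defaults approximate a
mildly noisy structural slice and are deliberately frozen; the generator is a
pure function of its config (seed included) and never perturbs the caller's
RNG stream.

What it does *not* emulate: real anatomy's long-range correlations, partial
volume effects, Rician noise statistics, k-space artifacts, or
scanner/protocol variability. Passing the desk-scale learning tests therefore
demonstrates that the architecture, gradients and optimizer work as designed
— not that published benchmark numbers on IXI/BraTS transfer, which would
require those datasets and accelerator-scale training and are explicitly out
of scope.

## Numerical choices and degenerate inputs

- Internal tensors are channels-last `(N, H, W, C)` for GEMM efficiency; the
  public API is channels-first `(N, C, H, W)`, converted at the boundary.
- Convolution is cross-correlation (as in mainstream frameworks); the weight
  indexing contract is documented in `conv_w_index()`.
- Identity collapses are asserted at 1e-6 in double precision; the bound
  allows for BLAS summation-order effects.
- Degenerate inputs fail loudly: constant volumes (normalization undefined),
  images smaller than the SSIM window, non-divisible dims at decimation,
  mismatched checkpoint configs (error names the first mismatched key),
  non-finite inputs, empty pair lists, NaN losses (abort with step/batch
  diagnostics).
- Splits are volume-level (all slices of a volume stay together) to prevent
  leakage between adjacent slices; sizes use largest-remainder rounding so
  10 volumes at 70/10/20 give exactly 7/1/2.

## Known limitations

- CPU training tops out around desk scale; the `"paper"`-profile recipe on
  256×256 volumes is expressed but not practical without an accelerator.
- FLOPs are reported informationally via `count_macs()` (plain convolution
  MAC convention); the published 81.3G figure uses an unstated convention
  and is not asserted against.
- The ablation toggles remove blocks structurally (fusion consumes the
  remaining branch); published per-ablation parameter counts are internally
  inconsistent and only the full-model budget is treated as authoritative.
- PNG export is 8-bit (the `png` writer's limit); use NIfTI output where
  full precision matters.
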