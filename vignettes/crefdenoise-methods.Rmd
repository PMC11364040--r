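---
title: "Cref-targeted denoising of cryo-EM maps: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cref-targeted denoising of cryo-EM maps: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The statistical model

Single-particle reconstructions are built twice from random halves of
the data, giving half-maps $M_i = S + N_i$ with a shared signal $S$ and
independent, zero-mean noise realizations $N_i$. Everything in this
package rests on three standard consequences of that model, all
evaluated per concentric Fourier shell $s$:

1. **Half-map FSC.** With signal and noise uncorrelated and the two
   half-sets on the same scale, the expected Fourier shell correlation
   between the half-maps is
   $\mathrm{FSC}_{\mathrm{half}}(s) = q(s) / (1 + q(s))$, where
   $q(s) = \mathrm{var}(S,s)/\mathrm{var}(N,s)$ is the spectral
   signal-to-noise ratio (SSNR).
2. **Cref.** The full-dataset map is the average of the half-maps, with
   noise power halved. The expected correlation between the full-dataset
   map and a *noise-free* map follows from the half-map FSC alone:
   $C_{\mathrm{ref}}(s) = \sqrt{2F/(1+F)}$ with
   $F = \mathrm{FSC}_{\mathrm{half}}(s)$. Inverting this at
   $C_{\mathrm{ref}} = 1/2$ gives $F = 1/7 \approx 0.143$, which is why
   0.143 is the gold-standard resolution threshold.
3. **Bias decomposition.** Writing a denoised half-map as
   $D_i = S + B + N_i^d$ (shared bias $B$, leftover noise $N_i^d$), the
   per-shell variances of all four components are linear combinations of
   the pairwise shell covariances of $(M_1, M_2, D_1, D_2)$.

The denoiser is trained self-supervised: the network input is the
half-map average, and the loss is the mean absolute difference between
$C_{\mathrm{ref}}$ and $\mathrm{FSC}_{FD}$, the FSC between the input
and the network output. Nothing in the loss requires a clean map. The
loss is differentiable; `cref_loss(..., grad = TRUE)` returns the
analytic gradient with respect to every output voxel (a Wirtinger
derivative through the FFT), which the training loop backpropagates
through the network.

### Assumptions, stated plainly

* Signal–noise independence holds only in expectation; a single map's
  noise realization can correlate with its signal. Training over many
  patches averages this out; single-map curves inherit the sampling
  noise.
* $C_{\mathrm{ref}}$ does not identify the noise-free map uniquely —
  many outputs satisfy the same curve. The loss is a consistency
  condition, not a reconstruction guarantee.
* The bias formulas additionally assume $B$ independent of $N$ and
  $N^d$, and $S$ independent of $N^d$. A denoiser that shrinks both
  half-maps by a shared per-shell factor violates these;
  `shrinkage_diagnostic()` detects that regime by testing whether
  $\mathrm{cov}(D_1, D_2) \approx c_1 c_2\,\mathrm{cov}(M_1, M_2)$ with
  $c_i = \mathrm{cov}(D_i, M_i)/\mathrm{cov}(M_i, M_i) < 1$. The
  `var(B)` combination itself is exactly invariant to $S$–$B$
  correlation: those cross terms cancel algebraically (this is
  unit-tested with deliberately correlated draws).

## Network and training parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `depth` | 5 | levels in each U-Net path; a 96³ patch contracts to 3³ |
| `base_filters` | 16 | filters of every convolution |
| `kernel` | 3 | 3×3×3 same-padded convolutions (odd, standard) |
| `leaky_slope` | 0.01 | LeakyReLU negative slope |
| `upsample_mode` | nearest | ×2 nearest-neighbour; cheap and checkerboard-free when followed by convolutions (the only implemented mode) |
| `lr0` | 3e-4 | Adam initial learning rate |
| `beta1, beta2, epsilon` | 0.9, 0.999, 1e-8 | Adam moments |
| `decay, decay_every` | 0.7, 10 | staircase schedule: `lr0 · 0.7^floor(epoch/10)`; "decays every ten epochs" is read literally as a staircase, not a smooth exponential |
| `epochs, batch` | 195, 6 | production-scale defaults |

The channel plan uses `base_filters` at every convolution (encoder,
bottleneck, and both decoder convolutions per level, whose input is the
2×-wide skip concatenation). With this plan the parameter count is a
closed-form sum over the layer list, which `count_parameters()` reports
and the tests verify layer by layer. Published descriptions of
comparable architectures sometimes quote totals that no assignment of
these hyperparameters reproduces; every width here is therefore
configurable rather than hard-coded, and the count is measurable rather
than asserted.

Training details: the batch loss is the arithmetic mean of per-patch
losses; shuffling is reseeded deterministically each epoch from the run
seed, so histories are bit-reproducible; there is no gradient clipping —
a non-finite loss aborts with a diagnostic. Held-out loss is recorded
per epoch for monitoring, but best-checkpoint selection is off by
default: the model is not tuned on held-out data, and the final-epoch
weights are returned.

### Per-patch Cref targets

The loss needs an $\mathrm{FSC}_{\mathrm{half}}$ curve. This
implementation computes it *per patch* from the two half-map patches —
self-consistent, always available, and it adapts the target to the local
signal content (an empty corner patch gets a near-zero target rather
than the whole map's). `cref_loss(cref = ...)` accepts an externally
supplied whole-map curve for users who prefer the deposited one.

## The patch pipeline

Maps are masked, standardized to mean 0 / sd 1 (statistics over all
voxels of the masked map — masking first, then standardizing; an option
restricts statistics to in-mask voxels), and tiled into non-overlapping
96³ windows from the origin, with a final partial window shifted back
flush with the boundary so every patch holds genuine data. Windows with
identically zero mask content are dropped. Standardization happens on
whole maps *before* tiling, so patch statistics reflect the map, not the
patch. Train/test splitting is at the *map* level: patch-level splitting
would place patches of the same map — the same signal — on both sides,
leaking the quantity being estimated. Patch edges are configurable; the
tests use 16–32 so that shells retain enough voxels for stable FSC at
small problem sizes.

## Numerical choices

* **Shell binning**: integer rounding of the centred Fourier radius in
  index units; shells 0..⌊N/2⌋; corner voxels beyond the Nyquist radius
  belong to no shell. Shell $s$ sits at frequency $s/(N \cdot
  \mathrm{voxel})$ in 1/Å.
* **DC handling**: shell 0 is computed but excluded from the integrated
  FSC and from the loss; standardized maps have near-zero mean, making
  it meaningless.
* **Hermitian residue**: the FSC numerator is real for real inputs up to
  rounding; the real part is taken.
* **Zero-power shells**: FSC is defined as 0 there (with a warning), so
  curves stay total.
* **Negative half-map FSC in Cref**: clamped to 0 before the square
  root; $2F/(1+F)$ is negative there and carries no signal.
* **Covariances**: per-shell mean Hermitian product without mean
  subtraction for $s \ge 1$ (shell means of Fourier coefficients of
  stationary fields vanish); the DC shell uses the mean-subtracted
  real-space covariance. Negative variance estimates (sampling noise)
  are reported raw and clamped at zero only for ratio curves, where
  floored denominators are flagged.
* **Non-cubic maps** are rejected for shell operations rather than
  silently reshaped; whole-map denoising accepts any shape.
* **Inference padding**: volumes are reflection-padded to the next
  multiple of $2^{\mathrm{depth}}$ and cropped back — reflection avoids
  the dark-border artifacts of zero padding.
* **Resolution estimation**: first crossing below the threshold,
  scanning outward from shell 1, linearly interpolated between shell
  centres; later re-risings are ignored. A curve that never crosses
  returns the Nyquist-limit sentinel ($2 \cdot \mathrm{voxel}$ Å).
* **Curve RMSE**: computed on the *squared* curves,
  $\sqrt{\mathrm{mean}[(F^2 - C^2)^2]}$, which is numerically stable
  where both curves approach zero.

## The synthetic generator: what it does and does not emulate

`make_phantom()` builds a ground truth from seeded Gaussian blobs in the
central 2/3 of the box; `make_half_maps()` adds two independent Gaussian
noise fields, either white (`noise_sd`) or Fourier-shaped per shell so
the realized SSNR hits a target exactly; `inject_bias()` produces
denoised-like maps $D_i = S + B + a N_i$ with one shared bias field,
either shaped to a per-shell `var(B)/var(S)` ratio or low-pass filtered
(bias concentrated at low frequency, the typical signature of learned
sharpening models). Realized spectra are recorded in the same
shell-covariance convention the analyzers use, so generator/analyzer
closure is exact up to sampling noise. Gaussianity is the standard
reconstruction-noise assumption and is what the FSC–SSNR relation needs
in expectation.

Not emulated: CTF modulation, projection geometry, B-factor envelopes,
solvent masking artifacts, alignment errors. Passing tests therefore
demonstrate the *statistical machinery* — FSC/Cref consistency, spectral
closure, variance recovery, optimization — not performance on
experimental maps.

### Noise mode for the training demonstration

The shaped-SSNR mode exists to verify the FSC–SSNR relation at an exact,
known SSNR. It is deliberately **not** used for the training
demonstration: shaping noise to a flat SSNR on a Gaussian-blob phantom
makes the noise spectrum decay as steeply as the signal's (a ~10⁶ range
across shells), and cutting 32³ patches then leaks low-frequency power
across shells strongly enough that a network can match the per-patch
Cref target through leakage alone, without denoising — a degenerate
optimum we observed directly (the model amplified high frequencies and
*reduced* held-out correlation with the truth). Real reconstruction
noise has a roughly flat spectrum — that flatness is precisely why SSNR
decays with frequency — so the training demonstration uses the white
noise mode (`noise_sd = 0.3` against blob amplitudes of ~0.5–2), under
which high-frequency shells are genuinely noise-dominated and the
trained network exhibits true denoising: higher real-space correlation
with the known truth than the input, and an FSC-to-Cref RMSE far below
the identity model's.

## Problem sizes used by the tests

Chosen so the whole suite runs in a few minutes on one core: oracle
comparisons on 16³–32³ volumes against a naive all-voxel triple-loop
implementation (agreement to 1e-10); spectral closure and decomposition
recovery on 64³ maps, asserting on shells with ≥ 500 Fourier voxels,
with tolerances derived from the sampling variance of shell means (±0.05
on FSC values; variance ratios recovered within 15%, estimated over the
qualifying shell band — single shells fluctuate ~±8% at that size, so
the band estimate is the meaningful quantity); and a training
demonstration with a depth-2 / 4-filter model on sixty 32³ patches for
20 epochs at batch 6. The production-scale defaults (depth 5, 16
filters, 96³ patches, 195 epochs) are exercised structurally (shapes,
counts, schedules) rather than by a full training run.

## Known limitations

* Training is CPU-bound single-threaded R/C++; it is a faithful,
  deterministic implementation of the optimization, not a
  high-throughput one. Production-scale runs would want a GPU port of
  the same loss.
* `var(N^d)` from the covariance decomposition understates leftover
  noise under correlated shrinkage (see the diagnostic above); ratio
  curves should be read alongside the flag.
* Per-patch Cref targets are noisy for small patches; the package
  accepts an external whole-map curve where that matters.
* The MRC reader covers modes 0/1/2/6 with the MRC2014 origin
  convention, which is what EMDB half-map depositions use; exotic
  header variants are out of scope.
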