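---
title: "Self-supervised denoising of cryoEM micrographs: model, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised denoising of cryoEM micrographs: model, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

CryoEM micrographs are extremely noisy: at typical exposures the
signal-to-noise ratio is around 0.1 (about −10 dB), because the electron
dose that a frozen specimen tolerates is small. Classical remedies are
ad-hoc low-pass filters, which trade signal for noise indiscriminately.
Supervised denoising networks would do better, but cryoEM has no clean
reference images to train on.

The way out is a property of direct-detector movies: each exposure is
recorded as many short frames, and each frame is an independent noisy
observation of the *same* underlying specimen signal. Summing the frames
with even indices and, separately, the frames with odd indices yields two
images `x_a`, `x_b` with identical signal and independent noise. A
denoiser `f` with parameters `θ` can then be trained on pairs alone
(the Noise2Noise construction): minimizing

* `E ||f(x_a) − x_b||²` (L2) makes `f` estimate the posterior **mean**,
* `E |f(x_a) − x_b|` (L1) the **median**,
* a smoothed L0 objective the **mode**

of the signal given the noisy input — all without ever seeing clean data.
In practice both directions are used: each minibatch minimizes
`0.5 * (loss(f(a), b) + loss(f(b), a))`.

This package implements that pipeline end to end in R: MRC2014 I/O,
even/odd pair generation, the denoiser architectures with their own
compiled convolution/backprop core, deterministic Adagrad training,
seam-free tiled inference, two SNR estimators, and a synthetic movie
generator that makes every stage testable offline.

## Architectures

| arch | structure | receptive field |
|---|---|---|
| `affine` | one 31×31 convolution, zero-initialized | 31 |
| `fcnn` | three 11×11 convs, 64 filters, leaky ReLU | 31 |
| `unet_small` | U-net, 3 pooling levels | 65 |
| `unet` | U-net, 5 pooling levels, first conv 11×11 | 257 |
| `unet3d` | 3D U-net, first kernel 7, default 3 levels | 59 |

The U-nets use an 11-wide (7 in 3D) first convolution, then per level a
2× max-pool followed by a 3×3 convolution; the decoder mirrors this with
nearest-neighbour upsampling, concatenation of the encoder skip at the
same resolution, and a 3×3 convolution; a final linear 3×3 convolution
maps back to one channel. Leaky-ReLU slope is 0.1 everywhere except the
output layer. Per-block filter counts are not prescribed by the original
design (it defers to an earlier reference), so the width is a single
`base_width` parameter (default 48) kept constant across levels, with
`2*base_width` channels entering each decoder convolution after
concatenation. The `constant` architecture (a single bias) exists as a
diagnostic: its L2/L1 optima are the target mean/median, which the test
suite exploits.

The affine model trained with L2 is exactly the linear least-squares
(Wiener) filtering problem; the acceptance suite verifies that Adagrad
training converges to the normal-equations solution.

**Receptive fields.** For pure convolution stacks the usual recurrence
`rf += (k−1)` holds. For the U-nets it does not: max pooling is not a
centered operator, and the measured influence footprint of the depth-5
U-net is larger than the recurrence suggests. `receptive_field()`
therefore propagates a 1D influence set through the actual layer graph
and maximizes over pooling alignments; tests compare it against a
brute-force pixel-perturbation oracle.

## Training recipe

Defaults follow the published recipe: Adagrad, learning rate 0.001, 100
epochs, 800×800 patches, minibatch 4, augmentation by right-angle
rotations and mirroring (the dihedral group — never interpolating
rotations). One epoch samples one patch per training pair, resampled
every epoch. Each half of a pair is normalized once at the whole-image
level to mean 0 and *population* standard deviation 1; the halves are
normalized independently, since they are independent observations (the
original leaves this open; sharing statistics changes results only at the
third decimal on synthetic data). Training is bitwise deterministic given
the model seed (initialization) and the config seed (sampling).

Choices the original leaves open, decided here:

* *Patch shrink rule*: on micrographs smaller than the patch, the patch
  shrinks to the image (with a warning), then down to a multiple of
  `2^depth` for pooled models so that backpropagation never crosses
  padding. 800 and 128 are already multiples; only sub-`2^depth` images
  are affected.
* *Epoch granularity*: one sampled patch per pair per epoch, shuffled.
* *L0 smoothing*: `(|d| + 1e-8)^γ` with γ annealed linearly 2.0 → 0.01
  across epochs; off by default.
* *Initialization*: zero for the affine model (as stated); fan-in-scaled
  uniform `U(±1/sqrt(fan_in))` for networks, seeded.

## Inference and the stitching guarantee

Full micrographs are denoised in patches (default 4000², with 500 px of
context) to bound memory. The whole image is normalized once, each padded
tile is pushed through the model, only the core of each output is kept,
and the stitched result is restored with the same statistics. When the
padding is at least `ceiling(rf/2)`, the stitched output equals the
whole-image forward pass — no seams. Two implementation details make the
guarantee exact here:

* tile origins and padding are rounded to multiples of `2^depth` for
  pooled models (`plan_tiles(..., align=)`), because max pooling is only
  translation equivariant for aligned shifts;
* border tiles are clipped at the image edge (not reflected), so the
  network's internal zero padding sees the same boundary there as in the
  whole-image pass.

The test suite asserts equality within 1e−5 for all four 2D
architectures and runs an unpadded negative control that shows the seams
the padding removes. Volumes follow the same scheme with cubic tiles
(default 96³) and default padding `ceiling(rf/2)`.

## SNR estimation

Two estimators, deliberately different in their assumptions:

* **Region SNR** — from hand-labeled signal/background rectangle pairs:
  per pair, signal power `s_i = (μ_signal − μ_background)²` (the mean is
  used to suppress noise in the estimate) and noise power `v_i` the
  population variance of the background region; the report is the mean
  of `10·(log10 s_i − log10 v_i)` in dB. Invariant to affine intensity
  rescaling. Annotations are a documented TSV of 0-based half-open
  rectangles.
* **Split-frame SNR** — from two independent observations of the same
  signal: with `p` their Pearson correlation, `SNR = p/(1−p)`, reported
  as `10·log10(p/(1−p))` dB. This is what lets denoising be measured
  without ground truth: correlate the denoised odd-frame micrograph with
  the untouched even-frame micrograph. The identity
  `MSE = 2 − 2·CCC` for normalized images links this estimator to the L2
  training objective and is asserted to 1e−10 in the tests.

Baselines: `lowpass_bin(image, 16)` is the 16× binning low-pass,
implemented as a Fourier band-limit at Nyquist/16 so the output stays
full-size for pixelwise comparison (the real-space block-average
definition would change the grid; the original does not specify the
operator). `lowpass_gaussian(image, 1/8)` multiplies the spectrum with a
radial Gaussian that attenuates to 0.5 at the cutoff — stated explicitly
because "Gaussian low-pass at 1/8 Nyquist" has no universal attenuation
convention. Dose-titration curves split a movie, keep the leading
`floor(fraction · n_frames)` frames of the odd half (fractions are of the
*total* dose, hence capped at 0.5), and report split-frame SNR per method
per dose. For figure display, `scale_display()` standardizes intensities
against the 16× low-passed reference and buckets z ∈ [−4, 4] into 256
levels, so raw and denoised panels share one scale.

## The synthetic world

`make_scene_2d()/make_scene_3d()` draw Gaussian blobs (sd = radius/2) of
amplitude `contrast` *below* a constant background — the phase-contrast
convention that particles are dark. `render_movie()` draws per-frame
noise: pure Gaussian readout, or Poisson shot noise at a per-frame count
scale plus Gaussian readout. The default fixture is 128² frames, 8
particles of radius 6 px, contrast 1, 40 frames, with the per-frame noise
sd calibrated by `noise_std_for_snr()` so the even/odd pair SNR is 0.1 —
the regime stated for real micrographs. `expected_pair_snr()` gives the
closed-form SNR of a rendered pair and serves as the oracle for the
estimator tests.

What the generator emulates: independent same-signal frames, low-count
shot plus readout noise, dose fractionation, particle-like smooth signal.
What it does not: CTF oscillations and defocus envelopes, detector
MTF/DQE, beam-induced motion, ice-gradient backgrounds, structured
(non-white) noise. A green end-to-end test therefore establishes that the
machinery is correct and that learning beats fixed filters *in this
stated world*; it does not certify performance on real detector data,
which the original measured on large public datasets with GPU-trained
general models.

## Numerical choices and limitations

* Population (n, not n−1) variance throughout — normalization and both
  SNR estimators share the convention.
* MRC2014: mode 2 (float32) written, modes 0/1/2/6 read and promoted;
  the float32 on-disk precision of summed micrographs is an assumption
  the original never states. A 3D MRC is a movie stack only when the
  caller says so; headers do not distinguish reliably.
* Convolutions use zero padding inside the network; edge effects are
  neutralized by inference-time patch padding, and the residual border
  effect of clipped edge tiles is quantified by the negative-control
  test.
* The 3D U-net defaults to 3 pooling levels (not the 2D model's 5):
  five levels would collapse a 96³ patch to 3³ at the bottleneck, and
  the original does not state that all five levels are kept in 3D. The
  depth is a flag.
* Desk-scale budgets: the acceptance experiments train a depth-3,
  width-16 U-net for 20 epochs on 64 synthetic pairs (≈6 min on one
  CPU) and an affine model for 100 epochs (≈2 min, plus ≈1 min for its
  normal-equations oracle). The depth-5 U-net is exercised at width 16
  in the stitching test for the same reason; the stitching property is
  width-independent.
* Training is in-memory; streaming inference for larger-than-RAM volumes
  is out of scope, as are frame alignment, gain correction, CTF
  estimation and particle picking.
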