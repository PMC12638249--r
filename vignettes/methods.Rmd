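---
title: "Coordinate-network compression of microscopy images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-network compression of microscopy images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`inif` stores an image not as pixels but as the weights of a small
coordinate network. Every pixel of an N-dimensional microscopy image (axes
drawn from T, C, Z, Y, X) is addressed by a coordinate vector normalized to
$[-1, 1]$ per axis; a sinusoidal multilayer perceptron (a SIREN)
$f_\theta : [-1,1]^D \to \mathbb{R}$ is fitted so that $f_\theta(c_i)
\approx v_i$ for all pixel coordinates $c_i$ and intensities $v_i$. The file
then contains $\theta$ plus a small self-describing header, and decoding is
evaluation of $f_\theta$ — at every grid point, at a single slice, at a
strided subsample, or at an arbitrary set of coordinates, all from the same
stored weights.

The default network has 7 weight layers: an input sine layer
($D \to W$), five hidden sine layers ($W \to W$) and a linear head
($W \to 1$). Each sine layer $l$ computes $\sin(\omega_l (W_l x + b_l))$
with its own trainable scalar frequency $\omega_l$, initialized at
$\omega_0 = 30$. Weights follow the standard SIREN initialization
(first layer uniform on $[-1/D, 1/D]$, deeper layers uniform on
$[\pm\sqrt{6/\mathrm{fan_in}}/\omega_0]$), biases start at zero. `depth = 2`
degenerates to a pure affine model, which is used as a convergence oracle in
the tests (full-batch descent must approach the closed-form least-squares
fit). We use $\sin$ rather than $\cos$; the two differ by a phase
expressible through the bias, so the choice is representationally neutral.

Intensities are min–max normalized to $[0, 100]$ before fitting (the source
bounds are the observed per-image minimum and maximum; optional percentile
clipping and per-channel modes exist but are off by default, since a single
global map preserves relative channel brightness in multichannel data). A
constant image maps to the lower bound with unit scale so the map remains
invertible. Training loss is computed in this normalized domain. An axis of
extent 1 maps to coordinate 0, the midpoint of the training range, where
the per-axis formula $-1 + 2i/(n-1)$ is undefined.

## Controllable compression ratio

The compression ratio is defined as uncompressed pixel bytes (extents ×
dtype bytes, container-independent) divided by the on-disk `.inif` file
size *including* all header metadata. Given a target ratio, the sizing
routine picks the **largest hidden width whose serialized container fits
the byte budget** `floor(raw_bytes / target)`. Because header fields that
are unknown before training (normalization bounds, checksum) are budgeted
at their worst-case rendered length, the written file can only be smaller
than planned, so the achieved ratio is guaranteed to be at least the
target. This guarantee is property-tested across random shapes, dtypes and
targets. Width is the only sizing degree of freedom at a fixed depth of 7;
depth is a configuration override.

## Training

The trainer is plain seeded minibatch gradient descent on the coordinate
grid: each epoch is a fresh permutation of all grid points consumed in
batches (the full grid when it is small), with the optimizer taken from a
registry. The default is Adam with learning rate $2.5\times10^{-3}$
decayed on a cosine schedule to $10^{-4}$, $\beta = (0.9, 0.999)$, and the
output bias initialized to the target mean so early steps fit structure
rather than the DC level. The schedule was selected on the synthetic
nucleus benchmark in this package: $10^{-3}$ undertrains at practical step
counts, $10^{-2}$ is unstable, and a floor of $10^{-4}$ keeps late steps
productive. The registry
also ships plain SGD and an extension hook with the same step signature,
which is where a learned optimizer would plug in; the package deliberately
ships hand-tuned defaults rather than pretrained optimizer weights, and no
learning-rate claim beyond "a robust default" is made. Default problem
sizes: 5000 steps and 65536-point batches for production use; the test
suite and the acceptance script scale these down (500–3000 steps,
4096–16384-point batches) to keep a single-CPU run in minutes — the
package treats those sizes as the study conditions for its own
property checks.

Forward and backward passes are hand-written dense linear algebra. Training
uses BLAS matrix products; decoding uses a deliberately different,
row-independent accumulation: optimized BLAS kernels choose different
blocking (and hence different floating-point summation orders) depending on
how many rows are evaluated, which would break the promise that decoding a
region of interest equals the corresponding selection of a full decode *bit
for bit*. The decode path therefore accumulates rank-one products in a
fixed order per output element, making every ROI evaluation independent of
batch shape. The analytic gradients are verified against central finite
differences; the comparison uses the norm-relative error
$\max_i |g_i - \hat g_i| / \max_i |g_i|$, the standard gradient-check
metric, because the entrywise ratio degenerates at near-zero components
(the finite-difference oracle's own $O(h^2)$ truncation error dominates
there).

## Guided losses

Two application-specific loss terms can be added to the pixel loss; the
total is always `mse + weight * guidance`, and weight 0 reproduces the
unguided trainer byte-for-byte.

**Segmentation guidance** preserves segmentability of thin structures. The
evaluation segmenter is a deterministic hard pipeline in the style of
filament-segmentation workflows: contrast clipping to
$[\mu - 1.5\sigma,\ \mu + 10.5\sigma]$ rescaled to $[0,1]$, Gaussian
smoothing ($\sigma = 1$), a bright-ridge response (negative
scale-normalized Laplacian of Gaussian at scale 1) thresholded at 0.01,
and removal of connected components under 20 pixels. The contrast bounds
are interpreted as standard-deviation offsets around the mean, the
convention of the published segmentation toolkit this pipeline follows.
This hard pipeline is not differentiable, so training uses a smooth
surrogate: the same frozen affine contrast map, smoothing and ridge
response (all circular convolutions, hence exactly self-adjoint, making the
hand-written gradient exact), followed by a sigmoid soft threshold
$\sigma((r - 0.01)/\tau)$. The training loss is one minus the soft IoU
$\sum s\,m / \sum (s + m - s\,m)$ against a constant (stop-gradient) mask
of the original; the trainer uses the original's *hard reference* mask as
that target — it is exactly the quantity downstream evaluation measures,
and on the filament benchmark in this package it outperforms targeting the
original's soft mask (which ties with unguided training once the trainer
is strong). Three surrogate choices matter and were diagnosed explicitly
during development:

* the contrast window is computed from the *original* image and frozen —
  the hard segmenter renormalizes adaptively to the image statistics, and
  letting gradients flow into (or ignore) that adaptation lets the
  optimizer "win" by warping global statistics while the hard-pipeline IoU
  collapses;
* the default temperature is warm ($\tau = 0.1$). A near-binary sigmoid
  ($\tau \lesssim 0.01$) concentrates all gradient mass on the decision
  boundary and the guidance term simply stops training. In a pure
  pixel-space experiment (gradient descent on the image itself), the warm
  surrogate drives the hard-reference IoU of a blurred filament image from
  0.68 to 0.97, while the saturated surrogate destroys it;
* binary reference targets give the soft branch an anchored, well-scaled
  pull; identity-style exactness properties (loss 0 at identity, 1 on
  disjoint structure) hold in the cold-temperature limit and are tested
  there.

Per training step, one Y–X plane (chosen uniformly by the seeded stream)
is rendered from the model and receives the guidance gradient. Empty∩empty
IoU is defined as 1: two masks that agree on absence agree perfectly.

**Perceptual guidance** targets compression of noisy acquisitions for which
a clean reference exists. Per step, a random patch rendered from the model
and an independently located patch of the reference are compared through a
feature network: the loss is the layerwise spatially averaged squared
channel-weighted feature difference. The default network is a fixed,
seeded 3-layer 3×3 convolutional stack with ReLU activations and unit layer
weights — a reproducible feature space, *not* a pretrained perceptual
model; externally trained networks can be passed through the same
interface. With identity features the loss reduces exactly to mean squared
error, which the tests exploit as an oracle.

## Hybrid mode with a codec prior

Hybrid compression gives a classic codec 90% of the byte budget
(`floor(split * raw/target)` bytes), fits the network to the residual
(affinely remapped into the training range, with the map stored in the
header) under the remaining budget, and records a per-slice decision:
a slice is overwritten by codec + residual only when that strictly improves
the chosen metric (PSNR by default; SSIM and user callables are accepted),
ties keeping the codec-only slice. Slices run along Z when present, else T,
else the whole image is a single slice. The built-in deterministic toy
codec (integer-factor downsampling plus uniform 8-bit quantization, linear
upsampling on decode) makes the hybrid path fully testable without any
external encoder; adapters for real video codecs plug in through the same
two-function interface. An adapter that overshoots its budget is tolerated
and reported through the achieved ratio — classic encoders' rate control is
approximate — and the residual fit then falls back to its nominal share of
the budget.

## File format

An `.inif` file is `"NIF1"`, a little-endian uint32 header length, a UTF-8
JSON header, and the weight payload: for each layer the weight matrix in
fan-in-major order then its bias, finally the per-layer frequencies, each
scalar as little-endian float32 (or float16 under a header flag, trading
precision for ratio). The header records shape, axes, dtype, normalization
parameters, architecture, seed, an optional hybrid block (codec id, split,
decisions, residual map, codec payload length and checksum) and a CRC-32 of
the payload. Corruption, truncation, wrong magic and unknown versions
raise distinct error classes. Reading a file reconstructs a model whose
forward evaluations are bit-identical to the serialized one, because the
trainer itself rounds weights to their storage precision before returning.

## Decoding rules

Decoded values are clipped to the training range, inverse-affine mapped,
clipped to the dtype range, and rounded half-to-even for integer dtypes.
Strided previews anchor at index 0 and take every s-th pixel, giving
extents `ceiling(n/s)`. Mask and index decodes return flat values with
their multi-indices in row-major order. All ROI modes are implemented as
coordinate selection followed by the same pure evaluation, which is what
makes the bit-exact self-consistency property hold by construction rather
than by tolerance.

## The synthetic generator: what it emulates, and what it does not

All fixtures are generated in code, seeded, and pure functions of their
arguments: nucleus-like volumes (non-overlapping ellipsoids with
chromatin-scale internal texture over a dim background), curvilinear
filaments with a periodic intensity modulation along their length (the
generator records the fiber center lines so tests can verify the stripe
period along the fiber by FFT), multichannel fields with a tunable
colocalization weight (validated through Pearson correlation), and a
Poisson–Gaussian noise model for low-illumination acquisition. Default
fixture extents are small (≤ 64³) so the suite runs on one CPU in minutes.

These fixtures emulate the *geometry and statistics* that matter for the
compression claims — sharp membrane-scale edges, sub-codec-Nyquist texture,
thin ridges, channel correlation, shot noise — but not optics: there is no
point-spread function, no anisotropic Z blur, no depth-dependent
attenuation, no real chromatin morphology. Passing the property suite
therefore demonstrates that the implementation behaves as specified under
controlled conditions, not that any particular quality number transfers to
real acquisitions.

## Numerical choices and degenerate inputs

* Constant images: normalization maps them to the range floor with unit
  scale; a linear output bias fits them exactly.
* Non-finite pixels are rejected at normalization; a non-finite training
  loss aborts with a diagnostic rather than restarting silently.
* Indices are 0-based and ranges half-open everywhere in the public API.
* Metric conventions: PSNR/SSIM run in source-dtype units with
  `data_range` equal to the dtype maximum (255 / 65535); float images fall
  back to the observed range. Identical inputs report the `Inf` PSNR
  sentinel. SSIM uses an 11×11 Gaussian window (σ = 1.5,
  k₁ = 0.01, k₂ = 0.03) and averages Y–X planes for higher-rank arrays;
  it was cross-checked to 10 decimal places against an independent
  reference implementation on seeded fixtures, and those values are frozen
  in the tests.
* The slice-decision tie rule keeps the codec reconstruction, so a
  zero-information residual can never degrade a hybrid file.

## Known limitations

* Training is CPU-bound dense linear algebra; wall-clock cost grows with
  batch size × width² × steps. Width beyond a few hundred is impractical
  without an accelerator backend.
* At the default (deliberately aggressive) learning rate, an occasional
  seed shows a mid-training loss spike it only partially recovers from;
  quality claims are therefore evaluated as medians over seeds. Global
  gradient-norm clipping was evaluated as a remedy and rejected: at any
  clip level tight enough to suppress the spikes it acted as a blanket
  learning-rate cut and lowered the final quality of every run.
* The guidance surrogate shares the hard segmenter's parameters but not
  its exact operator semantics (e.g. boundary handling is circular so the
  adjoint is exact); agreement is by construction approximate and is
  exercised by property tests, not bit-compatibility.
* Per-channel normalization stores one bound pair per channel but decoding
  of per-channel-normalized files is intentionally not wired through the
  single-map fast path; the default global map is the supported route.
* CR control is exact for the native format; hybrid files inherit any
  budget overshoot of the external codec, which is reported rather than
  corrected.
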