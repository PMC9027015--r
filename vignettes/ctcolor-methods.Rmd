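---
title: "Methods: chroma regression and exemplar transfer for grayscale CT-like images"
author: "ctcolor"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in ctcolor, the
parameters that matter, the numerical choices behind them, and what the
synthetic-data tests do and do not establish about behavior on real CT
images.

## The colorization problem

A grayscale image carries only luminance. In a perceptual color space
(CIE Lab or CIE Luv) luminance is an explicit channel *L* ∈ [0, 100],
and colorization reduces to predicting the two chroma channels — (*a*,
*b*) ∈ [-128, 127]² or (*u*, *v*) ∈ [-134, 220] × [-140, 122] — given
*L*. This factorization is what both methods in the package exploit: the
input's luminance is never invented, only chroma is.

All conversions assume sRGB primaries with the piecewise sRGB transfer
function and the D65 white point (2° observer). The reference white is
computed as the XYZ image of RGB (1,1,1) under the same matrix used for
the conversion, which makes the neutral axis map to exactly zero chroma
instead of inheriting rounding error from an externally tabulated white.
Inverse conversions clip out-of-gamut results to [0, 255] rather than
erroring, because predicted chroma routinely leaves the sRGB gamut.

## Automatic colorization (chroma regression)

### Architecture

The network is a linear stack of eight blocks. Every block holds two or
three 3×3 convolutions, each followed by a leaky rectifier (negative
slope 0.2), and ends in one batch-normalization stage. Downsampling is
by stride-2 convolutions only — there is no pooling anywhere — and
upsampling is nearest-neighbour ×2 followed by convolution, which avoids
the checkerboard artifacts of transposed convolutions. The default
channel progression is

    16, 16 → /2 32, 32 → /2 64, 64 → /2 128, 128   (encoder, bottleneck 128)
    ×2 64, 64 → ×2 32, 32 → ×2 16, 16 → 16, 16      (decoder)

followed by a 2-channel 3×3 convolution with tanh activation — the
output head — emitting chroma in [-1, 1]. The bottleneck therefore
carries 128 feature maps at 1/8 of the input resolution; the default
input size is 224×224 and any size divisible by 8 is accepted. The
progression above is one concrete instance of the block contract; any
spec satisfying the machine-checked invariants (8 blocks, 2–3
convolutions each, stride-2 downsampling only, spatial size restored at
the output, bounded 2-channel head) is accepted by `build_colorizer()`.

### Training

Targets are the true chroma channels divided by their half-spans (128
for *a*/*b*; 177 and 131 for *u*/*v*) so they live in the tanh range,
and the loss is the plain mean squared error on these scaled values. A
classification-over-color-bins formulation exists in the literature;
regression was chosen here because the network's contract is a direct
two-channel chroma prediction, and MSE is its canonical loss. The
optimizer is Adam with default learning rate 1e-3 (`training_config()`),
`steps_per_epoch` is derived as ⌈n/batch⌉ — with the default batch size
50, a 2,100-image dataset gives 42 steps; 30 images at batch size 10
give 3 — and every random draw (initialization, shuffling) flows from
explicit seeds, so training is bit-reproducible.

### Rendering and luminance preservation

At prediction time the grayscale input is resized bilinearly to the
network size, predicted chroma is mapped back to raw units and upsampled
to the original resolution, and the *original* lightness is re-attached.
Rendering uses lightness-preserving gamut mapping: pixels whose
(L, chroma) fall outside the sRGB gamut have their chroma scaled toward
the neutral axis by per-pixel bisection (22 iterations, i.e. chroma
resolved to ~2⁻²² of its span) until they fit. Naive RGB clipping would
silently change luminance for saturated predictions; bisection keeps the
luminance-preservation guarantee exact up to 8-bit quantization for any
model, trained or not.

## Exemplar transfer (Gram-matrix optimization)

The reference image's texture statistics are summarized per extractor
layer by the unnormalized Gram matrix G = FᵀF, where F is the N×C
matrix of feature activations (N spatial positions, C channels). The
style loss per layer is ‖G_target − G_reference‖²_F / (2NC)², the
content loss is the mean squared feature difference against the
replicated-gray target, and the total is
`style_weight · style + content_weight · content` (defaults 1 and 1e-4;
either term can be disabled, since the literature is ambiguous about
whether a content anchor is needed at all — both readings are
configurable). The (2NC)² normalization lives in the loss, not the
matrix, so `gram_matrix()` is integer-exact on integer fixtures and is
validated against a brute-force double loop.

The extractor is a contract, not a fixed set of weights: any stack of
size-preserving 3×3 stride-1 convolution blocks with optional 2×2 max
pooling between blocks is accepted. The default topology is the
five-block VGG-19 shape (conv counts 2, 2, 4, 4, 4; filters 64, 128,
256, 512, 512), working size 400×585. Weights load from a
user-supplied file when available; otherwise a seeded He-normal random
initialization is used. Random shallow features are a well-known, if
weaker, style statistic — they keep the package fully self-contained and
deterministic, and every structural and behavioral test holds under
them; with pretrained weights the same engine reproduces classical
feature-based transfer. Style layers default to the first convolution
of each block with equal weights; the content layer defaults to block
4's second convolution, following the topology's conventional choices.

Optimization is first-order descent on the output pixels, initialized at
the replicated-gray target and clamped to [0, 1] after every step. Two
numerical choices deviate from textbook fixed-step gradient descent,
both because the loss scale under a random extractor varies by orders of
magnitude across configurations: the descent direction is the gradient
scaled to unit RMS (so `step_size`, default 0.02, is a per-iteration
intensity budget in [0, 1] units), and the step is halved whenever the
recorded loss rises, which damps the overshoot oscillation a fixed step
sustains. Both choices are deterministic and cost no extra forward
passes. The target's luminance is *not* re-imposed on the result by
default — exemplar recoloring is allowed to repaint bright regions
wholesale, which is the intended behavior of reference-driven
recoloring — but `preserve_luminance = TRUE` re-attaches it.

## Synthetic data: what it emulates and what it does not

No public dataset accompanies this problem domain, so the package
generates its two data families procedurally. All generators are pure
functions of their spec, including the seed; multi-octave value noise
(seeded random lattices, bilinearly upsampled and summed with halving
amplitudes) is the only stochastic primitive.

- **Meat textures**: smooth noise blobs tinted by a per-class palette
  (pork: pink; steak: deep red with white marbling; lamb: red with an
  enlarged fat fraction, marbling ≥ 0.25; rotten: brown/red patchwork),
  with marbling drawn as level-set filaments of a finer noise field at
  an exact pixel fraction. The palette centroids are fixed documented
  constants — stand-ins chosen for class separability, not measurements
  of real meat.
- **Lung phantoms**: a bright soft-tissue ellipse on a dark background,
  two dark lung-field ellipses with vessel-like bright filaments, and,
  for the infected condition, Gaussian infiltrate patches confined to
  the lung fields. Default sizes are 224×224 (training resolution) and
  the phantoms expose their lung mask for testing.

These fixtures reproduce the *statistical* structure the methods rely on
(distinct hue families, marbling texture, dark-in-bright anatomy,
infiltrate brightening) but none of the photometric or anatomical
complexity of real meat photographs or CT slices: no lighting, no noise
model of a scanner, no window/level semantics, no pathology variety.
Passing tests therefore establish that the algorithms are implemented
correctly and behave as designed on data with the right structure — they
do not certify clinical image quality, and the headline quality numbers
reported on private photographic/CT datasets elsewhere are not
reproducible from synthetic data by design.

## Problem sizes and tolerances in the test suite

The suite favors small, seeded instances chosen to exercise every code
path: network tests run at 64×64 (the architecture is size-generic;
224×224 is exercised where the printed constants are checked), training
properties use 8 texture pairs for 12 epochs and a single-pair overfit
for 80 epochs at learning rate 3e-3, and exemplar properties use a
narrow (8–32 filter) extractor at 64×64 for 30 iterations. The overfit
recovery tolerance is a mean absolute chroma error below 8 Lab units
(observed ≈ 2.6) and a mean absolute RGB error below 12 levels
(observed ≈ 4). Gradient correctness is checked against central finite
differences at 1e-5 relative tolerance; Gram/loss vectorizations against
brute-force loops at 1e-10; SSIM against a windowed brute force at 1e-8;
color-space round trips within one 8-bit level over a 512-triplet grid.

## Known limitations

- CPU-only: default-scale exemplar runs (full VGG width at 400×585,
  200 iterations) take hours in R; practical runs scale the extractor
  width, working size or iteration count down via config.
- The exemplar method with seeded-random weights transfers color and
  coarse texture, not semantics; it will not align anatomical regions
  with reference regions.
- SSIM is computed on the lightness channel only, so it is insensitive
  to chroma errors by construction; PSNR (computed over RGB jointly)
  carries the chroma signal. SSIM can be negative on anti-correlated
  inputs; the formula is followed as stated, and non-integer exponents
  on a negative structure term would produce NaN rather than being
  silently sign-corrected.
- 8-bit PNG/TIFF/JPEG only; no ICC profiles, 16-bit depths, or DICOM.
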