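---
title: "Methods: unsupervised enhancement of light-sheet Raman stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised enhancement of light-sheet Raman stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Visible-wavelength (532 / 660 nm) light-sheet Raman microscopy of tumor
spheroids buys a large Raman scattering cross-section — the cross-section
scales as $1/\lambda^4$, so 532 nm excitation scatters about
$(660/532)^4 \approx 2.4\times$ more strongly than 660 nm — at the price of
a strong, spatially smooth autofluorescence background and shot/readout
noise that obscure molecular contrast. No paired clean/noisy training data
exist for such instruments, so supervised denoisers are not an option. This
package implements the computational side of that trade: an unsupervised
Deep Image Prior (DIP) denoiser embedded in a classical pre-/post-processing
chain, quality metrics, spectral baseline correction, and 3D reconstruction,
all exercised end-to-end on synthetic spheroid phantoms.

# The Deep Image Prior model

A randomly initialized convolutional encoder–decoder $f_\theta$ with skip
connections maps a *fixed* random tensor $z$ to an image. Fitting

$$\hat\theta = \arg\min_\theta \lVert f_\theta(z) - Y \rVert^2$$

against the single noisy slice $Y$ and stopping early yields a denoised
image: the convolutional parameterization fits coherent structure much
faster than i.i.d. noise, so intermediate iterates are clean
reconstructions. A sigmoid head constrains outputs to $(0,1)$, matching the
unit-normalized intensity convention used throughout the package.

## Architecture and optimization

No deep-learning framework exists in the supported R environment, so the
network and its backpropagation are implemented directly in
Rcpp/RcppArmadillo (`src/dip_net.cpp`): im2col + GEMM convolutions, nearest-
neighbour upsampling, hand-derived gradients, and Adam. Design choices that
matter:

* **Topology.** `depth` (default 4) stride-2 encoder levels of two 3×3
  convolutions each; 1×1 skip projections (4 channels) at every level except
  the deepest, concatenated into the decoder after nearest-neighbour
  upsampling; a 1×1 sigmoid head. Defaults: 16 base channels, a 16-channel
  input tensor $z$ with i.i.d. $\mathcal N(0, 0.1^2)$ entries. 16 rather
  than 32 base channels keeps a 128×128 slice fit under ~30 s on one CPU;
  quality on the evaluation phantoms was indistinguishable.
* **Instance normalization.** Each hidden convolution is followed by
  per-channel normalization with learnable scale/shift. This is load-
  bearing: without it, Adam at the customary step size (0.01) drives the
  sigmoid head into saturation on some seeds and optimization dies with the
  loss frozen. The reference DIP architectures rely on batch normalization
  for exactly this reason; on a single image the two coincide.
* **Early stopping, two mechanisms.** (1) A smoothed-loss plateau rule:
  the trailing `window`-iteration (50) moving average must improve by at
  least `min_delta` ($10^{-5}$) per window, `patience` (3) consecutive
  failures stop the run, and the iterate kept is the argmin of the smoothed
  loss. (2) A deliberately tight iteration cap (`iterations_max = 300`).
  The cap is not cosmetic: the MSE objective keeps decreasing while the
  network reproduces noise texture, so no loss-based rule can detect
  overfitting. Empirically (seeds 1–6, standard phantom) runs stopped near
  200–300 iterations score windowed SSIM 0.93–0.98 against ground truth,
  while runs allowed 500–600 iterations drop to 0.85–0.93 at equal PSNR.
* **Determinism.** All random draws (weights, $z$) come from R's RNG under
  `config$seed`; slice $k$ of a stack uses `seed + k - 1`. Identical
  configurations reproduce outputs bit for bit.
* **Padding.** Inputs are reflect-padded to a multiple of $2^{\text{depth}}$
  and cropped after fitting.

## What the training target is

The instrument narrative leaves open whether DIP fits the raw noisy slice
or the preprocessed one. Here the default pipeline fits the *preprocessed*
slice (background-subtracted, median-filtered): the ablation comparison
(below) shows preprocessing improves the final reconstruction, and fitting
the cleaner target is what makes that happen. The additive/subtractive
corrupted-pair generator (`make_noise_pairs()`) is provided as described,
but its coupling into the loss is unspecified at the source, so it is not
wired into training by default.

# The processing chain

Order: background subtraction (reference image) → median filter (3×3) →
optional circular ROI + CLAHE → DIP per slice → Fourier band-pass →
optional morphology. All steps preserve shape and the $[0,1]$ range, use
reflect padding, and can be switched individually (the ablation switches
`preprocess_enabled` / `postprocess_enabled` reproduce the three pipeline
variants: raw, DIP-only, DIP + pre/post).

Two defaults deserve justification:

* **CLAHE is off by default.** Contrast-limited adaptive histogram
  equalization deliberately remaps intensities; that is desirable for
  visualization but destroys the intensity correspondence that PSNR/RMSE
  against ground truth measure. It is implemented (tile-wise clipped
  histograms, bilinear mapping interpolation, mask-restricted) and
  switchable.
* **Band-pass defaults to a pure low-pass** (`low_cut = 0`,
  `high_cut = 0.45 ×` image size in cycles/image): after background
  subtraction the smooth fluorescence component is already gone, so the
  remaining job of the Fourier step is mild suppression of residual
  high-frequency noise. Setting `low_cut > 0` rejects DC and is the right
  configuration when no background reference exists.

**Background reference.** For phantom runs the reference is the phantom's
own autofluorescence field — the synthetic analogue of the specimen-free
reference acquisition the instrument workflow uses. For file input the user
supplies a reference stack, or the step is skipped.

# Quality metrics

* **PSNR** $= 10\log_{10}(\mathrm{MAX}^2/\mathrm{MSE})$, `Inf` reported at
  zero MSE, never a large finite stand-in.
* **SSIM** with $C_1 = (0.01\,\mathrm{MAX})^2$, $C_2 = (0.03\,\mathrm{MAX})^2$
  and a 7×7 uniform sliding window (the printed formula names no window or
  constants; these are the field's customary values). A `global` mode
  evaluates the formula once from whole-image moments — the literal printed
  form — and is what the brute-force oracle tests check.
* **RMSE** on unit-normalized intensities.
* **FRC**: per concentric frequency shell,
  $\mathrm{Re}\sum F_1 \bar F_2 / \sqrt{\sum |F_1|^2 \sum |F_2|^2}$ with
  single-bin shells and the DC bin excluded. The printed formula repeats
  $|F_1|^2$ in both denominator factors — an evident typo, since the
  expression would then not equal 1 for identical images; the standard
  symmetric denominator is implemented. The scalar summary is the mean over
  shells below half-Nyquist (the source reports scalar FRC values in
  0.7–1.0 without defining the reduction; the full curve is always
  retained). Shells with exactly zero power (e.g. Nyquist corners of
  symmetric images) are skipped with a warning.
* Every `metric_report` records which reference convention produced it:
  `noisy_input` (the instrument convention — no ground truth exists) or
  `clean_truth` (synthetic evaluation).

# Spectral baseline correction

The named tool is a Savitzky–Golay filter, which is a smoother, not a
baseline estimator. It is concretized as an iterative lower envelope:
repeatedly SG-smooth the running estimate (window 101 points, polynomial
order 2) and clamp it to the pointwise minimum with the previous estimate.
Peaks are progressively shaved off while the slowly varying fluorescence
background survives; `corrected = original − baseline`.

* **Convergence, not a fixed pass count.** With a fixed 20 passes the
  envelope is underconverged and re-correcting a corrected spectrum still
  moves peaks by several percent — violating the intended idempotence.
  The loop therefore runs to a fixed point (relative update $<10^{-8}$,
  cap 1000 passes; convergence is typically a few hundred cheap passes).
* **Operating regime.** Features wider than roughly half the window are
  treated as background and absorbed. With the default 101-point window on
  a 1 cm⁻¹ grid, the narrow CH₂/CH₃ bands (≈6–15 cm⁻¹) are recovered with
  centers within ±2 cm⁻¹ (the instrument's calibration tolerance) and
  amplitudes within 10%; a broad envelope like the full C–H stretch
  (3000–3400 cm⁻¹) requires a much wider window.
* **Edges.** SG edge samples come from polynomials fitted to the first/last
  full window (so ramps are reproduced exactly); peak quantification uses
  band maxima (`"integral"` mode available).

# The synthetic phantom world

The generator emulates what the instrument acquires, at the stated
conditions: a 300–400 µm spheroid (drawn uniformly unless fixed) inside the
635 µm × 635 µm field of view, 41 slices at 10 µm steps. Per Z plane the
sphere contributes a disk at its chord radius, with a brighter rim (outer
15% of the local radius, plateau 0.8 by default) over a dimmer core (0.5) —
the dense proliferating outer zone of real spheroids images brighter — with
two-pixel smoothstep roll-offs against aliasing. Corruption:
`noisy = clip(clean + background + noise, 0, 1)` with an independent
smooth background per slice (seeded white noise blurred to a 20 px
correlation length, scaled to amplitude 0.2) and i.i.d. Gaussian noise
(σ = 0.05 default; Poisson shot noise available).

Two deliberate modelling choices:

* **A base-intensity pedestal (0.15)** represents the camera offset plus
  medium scattering. It also keeps additive Gaussian statistics intact
  under clipping — with a zero background, `clip()` halves every negative
  excursion and the noise model would no longer be the one stated.
* **Not modelled:** the optical point-spread function, light-sheet
  thickness (the source reports both ~2 µm FWHM and ~8 µm beam waist —
  an inconsistency we note and do not resolve, since the phantom does not
  model sheet thickness), stripe/shadow artifacts, and depth-dependent
  attenuation. A green test therefore establishes that the *algorithmic
  chain* behaves as specified on data with the stated statistical
  structure, not that the instrument achieves these numbers on tissue.

The standard evaluation phantom (`standard_phantom_spec()`): 128×128,
spheroid at 60% of the field (381 µm), σ = 0.05, background amplitude 0.2,
phantom seed 42.

# Containers and formats

Multi-page TIFF is the working image container. No TIFF package exists in
the supported environment, so a minimal baseline codec (little-endian,
uncompressed, grayscale 8/16-bit unsigned and 32-bit float, one strip per
page) is implemented in `R/image_io.R`; the test suite cross-validates
round trips against an independent implementation. Spectral cubes are float
TIFF pages over wavenumber with a JSON axis sidecar. Pipeline configs are
JSON (no YAML parser in the environment). Stack order is page order is
ascending Z.

# Optics calculators

Pure functions for the instrument design relations: cross-section ratio
$(\lambda_2/\lambda_1)^4$, telescope magnification (implemented as printed,
$M = f_1/f_2$, with a `convention` switch for the textbook reciprocal),
Gaussian sheet profile $I_0 e^{-2x^2/w_0^2}\mathrm{sinc}^2(z/z_R)$, beam
width $w_0\sqrt{1+(z/z_R)^2}$, AOTF tuning $\lambda_c = \nu n / f$, and the
Rayleigh criterion $0.61\lambda/\mathrm{NA}$. Note the source's reported
~250 nm lateral resolution does not follow from 0.61·532/1.2 ≈ 270 nm; the
detection wavelength entering the criterion is unstated, so the calculator
is exposed as-is and no attempt is made to reproduce the 250 nm figure.

# Known limitations

* DIP on CPU is minutes per 128×128 slice at full budget; a 41-slice stack
  is an overnight-coffee job, not interactive. The implementation is
  single-threaded apart from BLAS.
* The iteration cap trades a little PSNR on slow-converging seeds for
  robust structural fidelity; for maximal PSNR on a known-clean target one
  would raise `iterations_max` and accept SSIM variance.
* The phantom's simplifications listed above; in particular FRC numbers on
  smooth phantoms are dominated by low-frequency shells.
* The baseline scheme cannot separate a broad Raman envelope from
  fluorescence of similar width — that is a physics limitation of any
  smoothness-based baseline, made explicit here by the window parameter.

```{r example}
library(lsraman)
run <- run_pipeline(pipeline_config())  # standard phantom, full chain
run$report$aggregate
```
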