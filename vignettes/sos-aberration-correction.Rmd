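---
title: "Learning-based speed-of-sound estimation and aberration correction for PA/US imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning-based speed-of-sound estimation and aberration correction for PA/US imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Photoacoustic (PA) image reconstruction is an acoustic inverse problem: the
time-reversal operator that refocuses recorded pressure traces onto the
optical absorbers needs the speed of sound (SoS) of the propagation medium.
Soft tissue is acoustically heterogeneous (roughly 1450 m/s in fat to
1580 m/s in muscle), yet reconstructions conventionally assume a single
value, typically 1540 m/s. The mismatch defocuses and displaces
reconstructed sources — aberration artefacts that widen point-source
profiles and lower the signal-to-noise ratio.

In a dual-modal PA/ultrasound (US) system that shares one linear array, the
pulse-echo US channel data are inherently co-registered with the PA frames
and carry information about the SoS distribution. `pasos` implements a
learning-based pipeline that exploits this: a fully convolutional
encoder-decoder regresses a pixel-wise SoS map directly from a single
plane-wave US RF frame, and the estimated map parameterizes the acoustic
medium of the time-reversal PA reconstruction. A sharpness-maximizing
autofocus over a single global SoS and the constant-1540 assumption serve
as baselines.

Everything is simulation-driven: digital phantoms, the acoustic forward
model, RF conditioning, network training, reconstruction and evaluation are
all part of the package, so the entire study can be reproduced from a seed.

## The acquisition model

The simulated probe has 128 elements at a 0.3 mm pitch (38.4 mm aperture)
and a 7 MHz centre frequency. Pulse-echo frames use a single 0-degree
plane-wave transmission of a 2-cycle Hann-windowed tone burst; the received
channels are time-gain compensated (0.5 dB/(MHz cm) at 1540 m/s, two-way
depth mapping), resampled to 20 MHz, trimmed to 1024 samples, and
normalized to zero mean / unit standard deviation per channel. The first 50
samples are zeroed (transmit cross-talk) and then populated with synthetic
transmit-interference segments; white Gaussian noise is added at a
per-channel SNR drawn from U[40, 80] dB (the acquisition protocol specifies
a noise floor 40–80 dB below the signal). The stage order is configurable;
the default places the zeroing before the system-noise injection so the
interference occupies the zeroed window, as it does in real acquisitions.

The forward solver integrates the first-order velocity–pressure system on a
staggered grid, 4th-order accurate in space and leapfrog in time, with a
graded exponential absorbing sponge of at least 10 cells on every edge
(residual in-grid energy after the wave exits is below 1 % of peak, see the
test suite). Heterogeneous sound speed enters through the bulk modulus and
sub-resolution scatterers through fractional mass-density perturbations.
Medium attenuation is applied as a frequency-independent per-step damping
evaluated at the transmit centre frequency; exact power-law absorption
would require spectral (fractional-Laplacian) operators and is deliberately
out of scope — at the 38 mm scale this approximation changes relative
amplitudes only, and the time-gain compensation stage is its inverse.

## Digital phantoms

Training phantoms follow a randomized ellipse model on a fixed
38.4 mm x 38.4 mm medium: a homogeneous background with SoS ~ U[1400, 1600]
m/s, one to five elliptical inclusions whose SoS sits 1–7 % above the
background, hyperechoic speckle contrast realized by raising the SoS of
about 10 % of the interior grid points by 7–11 % relative to the
background, and a scatterer field with a mean density of 3 per squared
transmit wavelength and amplitudes ~ U[-0.03, 0.03] applied to the mass
density (density scattering produces backscatter while leaving the SoS
ground truth clean). Ground-truth labels are 384 x 384 maps at 0.1 mm
holding the bulk per-region SoS — speckle and echogenicity perturbations
are excluded, because the regression target is the tissue-level sound
speed, not its microstructure.

Evaluation phantoms are structurally held out from training: pattern 1 is a
two-layer medium with a sine-deformed boundary (amplitude U[1, 4] mm, 1–2
periods) and uniform echogenicity; pattern 2 has straight isoechoic layers;
pattern 3 is a homogeneous background with hypoechoic ellipses (scatterer
amplitudes inside scaled by U[0.1, 0.5]). Evaluation SoS values reuse the
training bounds, and layers may be slower or faster than the background.
The reference protocol generates 40 phantoms per pattern.

```{r}
library(pasos)
spec <- sample_training_phantom(seed = 1)
sim <- desk_profile()
prep <- simulate_phantom_rf(spec, sim)   # medium, conditioned RF, label
```

## The estimator

The network maps a conditioned 128 x 1024 RF frame to a 384 x 384 SoS map.
The encoder has seven stages with non-square kernels whose width shrinks
from 3 x 15 to 3 x 3 in steps of two; the first four are strided
convolutions (the time axis contracts faster than the channel axis), the
last three add 2 x 2 max pooling. The decoder mirrors it with five
resize-convolutions (kernel widths growing 3 x 3 to 3 x 11), a bilinear
resizing stage to 384 x 384, a 3 x 3 convolution with batch normalization
and a final 1 x 1 convolution. The outputs of encoder stages 5 and 6 are
concatenated to the matching-resolution decoder stages. All convolutions
are Xavier-initialized and LeakyReLU (slope 0.1) activated.

Training minimizes the mean-square error by SGD (reference settings:
learning rate 1e-4, batch 10, train/validation split 0.9 applied per
phantom). Internally the network regresses the standardized quantity
(SoS - 1500)/100; predictions and logged RMSE are always in m/s. For
single-CPU studies the package provides narrow-width instances of the same
topology (`sosnet_config_small()`) and momentum SGD with a larger learning
rate — the desk-scale profile below trains in minutes.

Transfer learning to a shifted acquisition domain attaches a small residual
block on top of the frozen base: `y = base(x) + head(base(x))`, the head
being two 3 x 3 convolutions with a near-zero-initialized output so that
the augmented model initially reproduces the base to within 1e-3 m/s. Only
head parameters are updated (the base outputs are precomputed once), with
an epoch cap of 20 and an optional validation-plateau stop.

```{r}
ds <- simulate_rf_dataset(120, seed = 11, sim = sim,
                          config = phantom_gen_config(n_inclusions = c(0, 0)))
model <- build_sosnet(sosnet_config_small(width_scale = 32), seed = 5)
fit <- train_sosnet(model, ds, train_config(lr = 0.02, batch = 6,
                                            epochs = 14, momentum = 0.9,
                                            seed = 2))
sos_hat <- predict_sos(fit$model, ds$rf[1, , ])
```

## Reconstruction

Time-reversal reconstruction runs on a 788 (Z) x 768 (X) grid at 0.05 mm
(768 interior rows plus 10 absorbing points at the probe edge and its
opposite; 10-point absorbing strips also guard the lateral edges against
wrap-around). The probe maps at 5 grid points per element plus 1 kerf
point, so the 128 x 1024 acquisition frame is resampled to 640 x 4096 — a
factor 5 across channels (cubic spline) and 4 along time (exact
band-limited FFT interpolation) — and the first 150 of 1024 samples (600
after resampling) are zeroed. A 384 x 384 SoS map is interpolated
bilinearly to 768 x 768 to parameterize the medium; scalar SoS values are
broadcast. The reversed traces are re-emitted as a Dirichlet pressure
condition on the transducer line and the interior field after the final
step is the image. Negative lobes are retained; display normalization
(`pa_intensity()`) maps to [0, 1] by the maximum absolute value, and the
0.35 intensity threshold of the SNR metric presumes that normalization.

Scaled-down reconstruction grids keep the same geometry at a coarser pitch
(e.g. `recon_grid(0.15)` is 276 x 256). Forward-simulated initial-pressure
references are projected onto image coordinates with `project_p0()`, which
crops the absorbing rows above the probe line.

## Autofocus baseline

`autofocus_sos()` reconstructs the PA frame over a sweep of candidate sound
speeds (default 1400–1600 m/s in 5 m/s steps) and returns the sharpness
maximizer together with the sweep table. The default sharpness is the
normalized intensity power `sum(I^4)/(sum(I^2))^2`; the Brenner gradient is
available as an alternative and is evaluated on energy-normalized intensity
so that both metrics are invariant to global intensity scaling. Ties break
toward 1540 m/s. On homogeneous phantoms the sweep is unimodal and recovers
the true SoS within one step; on layered media a single global value cannot
serve both layers — the failure mode that motivates the pixel-wise
estimator.

## Evaluation metrics

* RMSE between SoS fields, per region and global; scalar estimators are
  broadcast (`rmse_sos()`).
* Region SSIM with single-window statistics over a mask and constants
  `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `L = 1` (`region_ssim()`). The
  evaluation harness references the reconstruction under the true SoS
  field; point-source comparisons reference the projected initial pressure.
* Lateral FWHM of point sources with linearly interpolated half-maximum
  crossings (`lateral_fwhm()`).
* SNR `20 log10(mu/sigma)` with the 0.35 intensity split between signal and
  background (`snr_db()`).

`evaluate_suite()` assembles these into a per-phantom, per-region,
per-method table comparing the constant-1540 assumption, the autofocus
baseline and the learned estimator.

## Desk-scale profile and what it shows

The reference acquisition geometry (1536^2 medium at 0.025 mm, 7 MHz)
needs GPU-scale computing for dataset builds. All bundled tests and the
acceptance script therefore run a desk profile that preserves the physics
and the geometry while scaling the discretization: the same 38.4 mm medium
on 128^2 (0.3 mm) or 256^2 (0.15 mm) grids, with the transmit frequency
scaled to 1 MHz / 2 MHz so the grid keeps at least ~5 points per
wavelength; reconstruction grids keep the matching pitch. Point sources
are smoothed into 2-cell Gaussian blobs to keep them band-limited on the
coarse grids (the arrival-time estimator, the analytic-signal envelope
peak, was checked against the exact 2D radial solution during
development). The learning study trains a narrow-width instance of the
architecture (`width_scale = 32`: 1–8 channels per stage) on 120
homogeneous-background phantoms for 14 epochs — about 4 minutes on one
CPU — and reaches a held-out map RMSE around 14 m/s, far below the
70.2 m/s closed-form RMSE of the constant-1540 baseline against
U[1400, 1600] backgrounds.

Passing at desk scale demonstrates that the pipeline is self-consistent:
the solver's travel times are sample-accurate, the time-reversal round trip
refocuses sources to within two pixels, aberration artefacts appear and are
corrected by the true SoS map, and the estimator extracts SoS information
from conditioned RF. It does not demonstrate clinical-grade generalization:
the desk profile's resolution cannot represent 7 MHz speckle statistics,
homogeneous-background training is a far easier regression task than the
full randomized ellipse model, and no real-probe effects (element
directivity, bandwidth, out-of-plane scattering) are simulated — which is
precisely why the transfer-learning stage exists.

## Numerical choices and degenerate inputs

* CFL number 0.3 against a global maximum SoS (default 1800 m/s) keeps the
  solver time step fixed across a dataset so every phantom records at the
  same rate.
* The anti-aliasing low-pass before 20 MHz decimation is a zero-phase FIR
  (Hamming design, cutoff at 0.9 x the output Nyquist, transition 10 % of
  the output Nyquist), followed by cubic-spline evaluation on the output
  clock; output frames are truncated or zero-padded to exactly 1024
  samples.
* All-zero RF channels are left at zero by `normalize_channels()` and
  flagged in metadata rather than dividing by a zero standard deviation.
* Ellipse overlap is resolved by listing order (later inclusions
  overwrite); layers rasterize before ellipses.
* Every stochastic stage draws its seed from a single top-level seed
  through named substreams (`substream_seed()`), so phantom geometry,
  speckle, echogenicity and noise can be varied independently yet
  reproducibly.
* SoS map predictions are returned unclipped; values outside [1300, 1800]
  would violate the reconstruction grid's stability bound and are rejected
  there with an explicit error.

## Known limitations

* The solver is 2D, linear and lossless apart from the uniform damping
  approximation; shear waves, nonlinearity and power-law dispersion are out
  of scope.
* At 4.7–6 points per wavelength the 4th-order stencil leaves ~0.3–1 %
  numerical dispersion for broadband pulse-echo content; differential
  (cross-channel) timing stays within a 20 MHz sample, and the acceptance
  checks quantify the absolute accuracy on the PA path. Absolute
  envelope-peak arrivals converge to about one 20 MHz sample between grid
  refinements at these resolutions (leapfrog and stencil phase errors have
  opposite signs and only cancel asymptotically), matching the +-1-sample
  travel-time tolerance the package targets.
* The shipped system-noise bank is synthetic (band-limited bursts confined
  to the first 50 samples); real banks load as plain matrices.
* `fine_tune()` adapts only the residual head; it corrects systematic
  domain shifts (gain, bias, pulse-shape changes) but cannot re-learn
  features the frozen base never extracted.
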