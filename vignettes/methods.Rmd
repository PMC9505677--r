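---
title: "Methods: simulating, calibrating and classifying hyperspectral biofouling images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, calibrating and classifying hyperspectral biofouling images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`hsifoul` quantifies marine biofouling on coated test panels from
hyperspectral images. A hypercube stacks 63 quasi-monochromatic images
acquired by scanning a liquid crystal tunable filter (LCTF) from 420 to
730 nm in 5 nm steps; each pixel therefore carries a full reflectance
spectrum. The pipeline is: raw counts → pixel-wise reflectance calibration →
Savitzky–Golay smoothing → annotated spectral library → standardized PCA →
per-pixel neural-network classification → confusion metrics and per-class
coverage. A radiometric forward simulator stands at the head of the pipeline
so that every downstream stage can be exercised, and its recovery verified
against exact ground truth, without instrument hardware.

## The forward model

Counts in channel $c$ (filter center wavelength $\lambda_c$) are

$$I(x,y,c) = t_{exp}(c)\Big[I_d(x,y) + G\int I_s(x,y,\lambda')\,
e^{-2\alpha(\lambda')d_w}\,R(x,y,\lambda')\,\tau_{TF}(\lambda',\lambda_c)\,
\tau_O(\lambda')\,\Re(\lambda')\,d\lambda'\Big],$$

clipped to $[0, 2^{14}-1]$. The quadrature runs on an internal fine grid of
1 nm over 400–750 nm (rectangle rule; the grid is uniform so this matches
the trapezoid rule away from the kernel truncation). Assumptions inherited
from the physical setup: parameters constant over one exposure, no
extinction in air, a homogeneous two-way water path $2d_w$, negligible
stray/Fresnel contributions, and a purely per-pixel geometry (the
panel-to-sensor coordinate transform is taken as the identity, since
spatial warping is irrelevant to per-pixel spectral classification).

One typesetting ambiguity in the published description of this class of
models is whether $t_{exp}$ multiplies only the dark term. Physically both
dark charge and photocharge accumulate over the exposure, so the simulator
applies $t_{exp}$ to both; calibration is insensitive to the choice because
all three cubes of a calibration set share the exposure plan.

### Instrument curves and their defaults

* **LCTF** (`lctf_model()`): FWHM rises monotonically 6.8 → 14.4 nm and
  peak transmission 0.72% → 23.6% across 420–730 nm. Only the endpoints of
  both curves are published, so both are interpolated linearly in center
  wavelength; the passband shape itself is unpublished and is modeled as a
  unit-peak Gaussian truncated at ±3σ.
* **Illumination**: a white-LED spectrum (narrow blue pump near 450 nm plus
  a broad phosphor band near 600 nm) times a separable spatial profile —
  uniform vertically, inverse-square falloff toward the left of the frame
  emulating a source tilted ~15° off the imaging axis
  (`tilt_falloff = 0.35` default, the fractional distance increase across
  the frame).
* **Water** (`water_model()`): a smooth pure-water-like attenuation curve,
  near zero in the blue-green and rising steeply toward 730 nm, fully
  overridable by a user table; default one-way path `d_w = 0.4` m (a panel
  at the back of a ~0.4 m tank).
* **Sensor**: EM gain `G = 20`, well depth 26,000 e⁻, 14-bit ADC, dark
  current 40 counts/s, read noise 2 counts. The output-node conversion is
  fixed so that at the configured gain the ADC range spans the full pixel
  well — the configuration that actually exploits the advertised dynamic
  range; with it, a pixel near full scale integrates ~2 × 10⁴
  photoelectrons.
* **Noise model** (unpublished in the source instrument, so a design
  choice here): Poisson-limit shot noise with the EM excess factor
  $\sqrt{2}$ (Gaussian approximation at these electron counts), Poisson
  dark counts, Gaussian read noise; one seeded generator; `noise = FALSE`
  yields deterministic, unquantized counts so algebraic identities can be
  tested exactly. With noise on, counts are rounded to integers.

### Exposure planning

Each channel is acquired in its own shot, so `plan_exposures()` sizes
$t_{exp}(c)$ per channel such that the brightest pixel of a flat reference
target reaches `target_fill` (default 0.8) of the ADC ceiling. The sizing
deliberately uses the signal term only (excluding dark current), which
makes the plan exactly inversely proportional to source radiance and
reference reflectance — a linearity that is also tested. Exposures come out
largest at the spectral extremes (low LCTF transmission and LED output in
the blue; water absorption, LED rolloff and sensor rolloff in the red),
reproducing the qualitative pattern of channel-wise exposure adaptation in
staring systems.

## Synthetic scenes and endmembers

`generate_endmember()` builds class reflectance curves as a baseline plus
Gaussian peaks minus Gaussian absorption dips, with feature placement
following the field signatures: chlorophyll-a dips at 450 and 665 nm in all
algae, the red-algae satellite dip at 615 nm, reflectance peaks at 545 nm
(green), 570 nm (brown, flatter and darker), 590/640 nm (red), a 720 nm
autofluorescence-plus-scattering peak (strongest in red algae), a flat
white panel near 45%, mussels near 4% with a slight rise toward the red,
and algae means below 16% over 420–700 nm. Amplitudes and widths are the
package's own parameterization, chosen once so that numeric extrema of the
generated curves fall inside the cited feature windows.

The model contains no emission term, yet chlorophyll autofluorescence makes
algae *appear* brighter at 720 nm than elastic scattering alone would; as
the measurement itself reports this as apparent reflectance, the 720 nm
feature is emulated as a reflectance peak. This is the one place where the
simulator knowingly bends radiometry to match what the instrument sees.

Variability has three seeded levels: per-specimen brightness and dip-depth
jitter at endmember generation (log-normal, defaults 0.05 and 0.10),
per-pixel log-normal brightness jitter within a scene (default 0.08,
emulating density/orientation/health variation), and sensor noise. Species
of the fine scheme (e.g. *Ulva* and *Zostera* within green algae) share
their color group's spectral construction and differ **only** by specimen
jitter — which is precisely why species-level classification must degrade
relative to color-group classification on these data.

What the generator does **not** emulate: mixed boundary pixels (every pixel
is spectrally pure, so edge confusion — a known error source on real
panels — cannot arise), intergrown or overlapping organisms, spatial
texture, water-column scattering and fluorescence from suspended matter,
and instrument-response deconvolution. Passing tests therefore demonstrate
correctness of the pipeline's machinery and its behavior under the modeled
physics, not field performance on real panels.

## Calibration

`reflectance_transform()` applies
$R = R_{ref}(I - I_d)/(I_{ref} - I_d)$ per pixel and channel. Because
numerator and denominator share every multiplicative spatial factor
(illumination profile, filter non-uniformity), the transform is invariant
to any positive illumination field — the flat-field property, verified to
float rounding. Numerical guards, all recorded per entry in a flag array
rather than silently applied:

* denominator $I_{ref} - I_d \le \varepsilon$ (default 10 counts): entry
  invalid (`NA`), never a huge ratio;
* saturated scene or bright-field counts: invalid;
* negative numerator (noise pushing counts below dark level): clipped to 0
  but kept usable, with its own flag.

Smoothing uses `signal::sgolay` (order 2, nine channels = 45 nm at 5 nm
sampling). Edge channels are fitted with the polynomial of the first/last
window (the off-center rows of the projection matrix) rather than padded.
Invalid entries are bridged by linear interpolation before filtering and
remain flagged afterwards. The workflow order is fixed: calibrate → smooth
→ annotate.

## Library, PCA, classifier

Libraries are assembled deterministically (row-major pixel order within
each rectangular ROI), keep per-sample provenance (cube, pixel, ROI), and
are never rebalanced by default — matching the heavy class imbalance of
real collections; `subsample_per_class()` (seeded, default cap 2000) exists
for exploratory plots only. `split_spatially_disjoint()` partitions by
provenance cube so training and test pixels can never be spatial neighbors.

PCA standardizes with training mean and standard deviation (zero-variance
channels get unit scale and a flag), orders components by explained
variance, and fixes signs so each component's largest-magnitude loading is
positive. Both the exploratory PCA and the classifier's input PCA use the
same standardization — the natural reading where the source is silent.
Component selection keeps the smallest count whose cumulative explained
variance reaches 99.99%.

The classifier is a single hidden layer of 100 rectified-linear units with
softmax output — wide rather than deep. The original training toolbox's
loss, optimizer and schedule are unrecoverable, so the package uses the
standard choice for this architecture: multinomial cross-entropy, no
regularization by default, seeded He-style initialization, full-batch
L-BFGS (`stats::optim`, default 300 iterations). Training is deterministic
given seed and data. Prediction is purely per-pixel (commutes with spatial
permutations); score ties break toward the lowest class index;
cross-validation is stratified with seeded fold assignment. Hyperparameter
search is deliberately out of scope.

## Numerical and interface choices

* On-disk cubes are ENVI-convention text headers plus band-sequential raw
  binary, doubles for bit-exact round trips; label rasters are single-band
  ENVI byte images with a sidecar text legend. BIL/BIP interleaves are
  converted on read only. (The original acquisition software's internal
  format is undocumented; ENVI is the neutral de-facto standard.)
* Coordinates are 0-based, row-major; rectangles are half-open
  $[r_0,r_1)\times[c_0,c_1)$, so areas are exact products.
* Reflectance is stored as float and may slightly exceed 1 (the 720 nm
  apparent-reflectance peak can exceed a 10% standard's scale).
* The global pipeline seed fans out into per-stage sub-seeds drawn once, so
  stages are independently reproducible; artifacts carry seed and config
  hash.
* Saturated/invalid pixels are excluded from libraries, classified as the
  reserved invalid code 0, and excluded from confusion and coverage
  denominators.
* Reports print percentages to two decimals; full precision is kept
  internally, and model/PCA serializations write 17 significant digits so
  a reloaded model predicts identically.

## Problem sizes

The packaged demonstration and the verification suite use scales chosen to
exercise every code path at full spectral resolution while remaining quick
on a single CPU: 63-channel cubes throughout; 120 × 160 px frames
(~9,600-sample six-class libraries) for the end-to-end runs; 64 × 64 px for
calibration round-trip measurements; 80 × 100 px for the exact-coverage
run; libraries of tens to hundreds of samples per class for classifier
unit tests. Monte-Carlo checks (signal-to-noise scaling, smoothing variance
reduction, ellipse containment) use 10⁴–2×10⁵ draws.

## Known limitations

Beyond the generator's idealizations listed above: no spectral unmixing of
mixed pixels; no spatial-spectral (convolutional) models; no
instrument-response deconvolution; no bootstrap uncertainty on accuracy or
coverage; coverage is a pixel ratio and inherits any segmentation bias at
object boundaries. The species-level scheme is expected to remain weak
whenever species share pigmentation — the spectra alone do not carry
taxonomic identity.
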