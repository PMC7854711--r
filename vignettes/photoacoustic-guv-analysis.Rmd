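---
title: "Quantifying photoacoustic-wave-mediated GUV permeabilization with pawkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying photoacoustic-wave-mediated GUV permeabilization with pawkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pawkit)
```

## The measurement problem

Pulsed-laser excitation of a piezophotonic film — a strong optical absorber
(carbon nanotubes, or a porphyrin such as MnTPP in polystyrene) embedded in
or coupled to a high-thermal-expansion matrix (PDMS) — deposits heat faster
than the material can expand or cool, and the resulting thermoelastic stress
launches a broadband, mostly compressive ultrasound pulse. When such waves
reach giant unilamellar vesicles (GUVs), they can transiently permeabilize
the phospholipid bilayer: fluorescent cargo (FITC-dextran, GFP) leaks out
while the vesicle survives. Three instruments observe this, and each needs
its own quantitative chain:

* a **Mach–Zehnder interferometer** images the wave as fringe bends, from
  which a 2D pressure map must be reconstructed;
* a **needle hydrophone** (or high-frequency contact transducer) records
  time-resolved voltage traces that must be calibrated to pressure and
  summarized;
* a **fluorescence time-lapse microscope** records GUV interiors whose
  intensity decay encodes the release kinetics.

`pawkit` implements the three analysis chains plus the closed-form
transduction physics, and — because raw instrument data from such
experiments are rarely published — a seeded synthetic-data module that
generates every input with known ground truth. The package's validation
strategy is forward–inverse closure: simulate with known parameters,
analyse, and require the estimates to return the truth.

## Transduction physics

The physics module is a set of closed forms with unit-bearing interfaces
(pressure MPa, fluence mJ/cm², lengths µm, times ns; SI internally):

* Napierian absorption coefficient from decadic absorbance,
  $\mu_a = 2.3\,A/l$. The 2.3 is the conventional rounding of $\ln 10$, so
  Beer–Lambert consistency ($e^{-\mu_a l} = 10^{-A}$) holds to ~0.1% per
  absorbance unit, and the tests assert exactly that tolerance rather than
  float equality.
* Grüneisen parameter $\Gamma = c_s^2 \beta / C_p$, the heat-to-pressure
  conversion efficiency.
* Absorber regime: "thin" when the optical penetration depth $1/\mu_a$ is
  below the acoustic transit length $c_s \tau_L$ during the pulse, with
  $p_{max} = \Gamma E_L / (c_s \tau_L)$; "thick" otherwise, with
  $p_{max} = \Gamma E_L \mu_a$. The boundary case $1/\mu_a = c_s\tau_L$ is
  assigned to "thick" — the regime definitions are strict inequalities, so
  the tie needed a convention, and the thick formula is the conservative
  (lower-pressure) choice at that point.
* Interface intensity transmission $T = 4 Z_1 Z_2/(Z_1+Z_2)^2$.
* Mechanical Index $MI = p_r/\sqrt{f}$ in MPa/√MHz (the standard
  regulatory definition; peak rarefaction pressure over the square root of
  centre frequency), flagged above the 0.7 cavitation-risk threshold.

For composite CNT–PDMS films the Grüneisen parameter of the PDMS matrix is
the one that matters physically (the nanotubes conduct heat but barely
expand; PDMS launches the wave), so the API takes a user-supplied material
parameter set rather than attempting composite mixing rules. No film
parameter set bundled here claims to predict the measured peak pressures of
real films — transduction efficiency is not modelled.

## Interferogram inversion

The pumped/reference interferogram pair is demodulated with the standard 2D
Fourier-transform method:

1. locate the carrier sideband as the largest spectral peak outside a DC
   exclusion disc (default radius 3 cycles/image), restricted to the
   half-plane of positive column frequency so the sign of the recovered
   phase is deterministic (compression gives positive phase; a `flip_sign`
   flag covers the opposite interferometer geometry);
2. apodize the sideband with a radial Hann window whose default radius is
   half the carrier-to-DC distance — large enough to pass the pulse's
   spatial spectrum, small enough to exclude DC and the conjugate sideband;
3. shift the sideband to DC, inverse-transform, and take the argument;
4. unwrap with sequential (Itoh) 1D unwrapping along columns followed by
   row alignment. This is reliable for the smooth, low-noise phase maps
   that survive the Hann filter; strongly noisy or discontinuous phase
   fields would need a quality-guided unwrapper, which is out of scope.

Subtracting the reference phase and removing a residual fitted plane
(offset + tilt) over a quiet region — by default the first 10% of rows,
the margin farthest from the source in the package's conventions — gives
the acoustic phase change $\Delta\varphi$, and then

$$\Delta n = \frac{\Delta\varphi}{2\pi}\frac{\lambda}{l}, \qquad
  \Delta\rho = \frac{\Delta n}{0.322}\ \mathrm{g/cm^3}, \qquad
  P = \frac{k_0}{n}\left[\left(\frac{\rho}{\rho_0}\right)^{n} - 1\right] + P_0 .$$

The optical path is treated as uniform across the liquid layer
(line-of-sight average); no tomographic inversion is attempted. Reported
pressures are gauge ($P - P_0$) in MPa.

**Tait constants.** The conversion names the Tait equation but published
constants vary; the package defaults to water at 20 °C:
$\rho_0 = 0.9982$ g/cm³, $n = 7.15$, $k_0 = \rho_0 c_s^2$ with
$c_s = 1482$ m/s, $P_0 = 101.325$ kPa — all overridable via `tait_eos()`.
In the small-signal limit the conversion reduces to the linear acoustic
relation $P = c_s^2 \Delta\rho$ (within 1% for $|\Delta\rho|/\rho_0 <
10^{-3}$), which the tests assert numerically; a 1 MPa pulse corresponds to
$\Delta\rho \approx 4.6\times10^{-4}$ g/cm³ and an embedded fringe phase of
about 4.6 rad at $\lambda = 400$ nm, $l = 2$ mm.

**Sampling choices.** The synthetic default geometry is a 256 × 256 grid at
1 µm/px with a carrier of 0.25 cycles/px. These were chosen so that the
spatial spectrum of a 36 µm FWHM pulse sits well inside the Hann window:
the windowed demodulation is a low-pass operation, and coarser sampling (or
a slower carrier) visibly biases the recovered peak low. At these defaults
the noise-free forward–inverse round trip recovers a 1 MPa peak to within
about 1.6% and the FWHM to within 0.4 µm; the residual bias is the
window's unavoidable attenuation of the pulse's high spatial frequencies.
Fringe noise at 20 dB SNR (noise sd = one tenth of the fringe modulation
amplitude) degrades this to a few percent.

FFT-based demodulation assumes periodic boundaries; the generators use an
integer number of carrier cycles per image and keep the pulse away from the
edges, which real interferograms approximate by windowed ROIs.

## Hydrophone waveforms

Calibration is frequency-domain deconvolution: divide the trace's FFT by
the manufacturer sensitivity (V/MPa) evaluated at each bin frequency and
invert. Outside the calibrated band (typically 1–30 MHz) the sensitivity is
held at its band-edge value. Flat extrapolation is deliberate and
conservative: photoacoustic pulses contain components beyond the calibrated
band, and inventing an out-of-band response would fabricate pressure. The
consequence — possible slight underestimation of peak pressures when energy
lies out of band — is inherent to the calibration data, not the code.

Metrics are computed after subtracting a baseline (median of the first 10%
of samples): peak compressive pressure, peak rarefaction magnitude searched
from the compressive peak to the end of the trace (photoacoustic pulses
carry their rarefaction as a trailing tail), temporal FWHM by linear
interpolation at half maximum, spectral centroid as centre frequency, and
the compression/rarefaction ratio. Metrics are defined on calibrated
traces; the uncalibrated trace's FWHM would differ through the sensitivity
curve's shape.

## GUV release kinetics

Detection uses Otsu's global threshold per frame (with an absolute
override), connected-component labelling, and equivalent-radius filtering;
the interior mean intensity is taken over the mask eroded by one pixel so a
bright membrane rim does not contaminate the interior signal. Tracking is
greedy nearest-neighbour linking with a displacement cap — gel-immobilised
GUVs are essentially stationary, so globally optimal assignment would be
over-engineering; ambiguous jumps beyond the cap terminate tracks rather
than risk mislinking. Background correction subtracts the per-frame mean of
a GUV-free rectangle, which removes frame-wide offsets and drifts exactly
and makes the release fraction invariant under global gain and offset
changes.

The release fraction is $1 - I_t/I_0$ with $I_0$ the background-corrected
intensity of the first frame, so the curve starts at exactly zero. Fitting
uses untransformed nonlinear least squares of $M_t/M_\infty = k t^n$
restricted to $0 < \text{fraction} < 0.6$ (the power law's validity range),
with log–log regression providing starting values and standard errors taken
from the Jacobian. Complete release at infinite time is assumed — the
fraction is used directly, with no fitted plateau. Fits can be per-vesicle
or on the frame-wise pooled mean curve; the fit object records which mode
was used. Group comparisons use the classical pooled-variance two-tailed
t-test with means ± SEM.

The default kinetics, $n = 0.53$ and $k = 0.25/900^{0.53} \approx
6.8\times10^{-3}\,\mathrm{s}^{-n}$, give 25% release over a 900 s exposure
— the regime in which these measurements operate, between Fickian diffusion
($n = 0.43$ for a sphere) and zero-order release ($n = 1$).

## What the synthetic data do and do not emulate

* **Pressure pulse template**: an asymmetric raised-cosine — a compressive
  lobe whose FWHM equals its half base width, with an attached inverted
  trailing lobe at `peak/rarefaction_ratio` — reproducing the steep rise,
  narrow width and small trailing rarefaction of thermoelastic pulses
  (defaults: 1 MPa / 36 µm spatially; 7 MPa / 25 ns / ratio 10 in time).
  It is a kinematic template at the observation plane: no diffraction,
  attenuation or nonlinear propagation is simulated.
* **Interferograms**: ideal cosine fringes with the phase of the forward
  chain (exact closed-form Tait inversion
  $\rho = \rho_0(1 + nP/k_0)^{1/n}$ — the power-law form inverts
  analytically, so no iteration is needed) plus optional white Gaussian
  noise. Real fringes add speckle, vibration drift and shot noise; only
  the white-noise component is emulated, which is why the quiet-region
  plane removal matters in both worlds.
* **GUV movies**: stationary uniform discs whose interior follows
  $B + I_0\max(0,\, 1 - k t^n)$ over a constant ambient level, with
  per-pixel Gaussian noise at SNR 20 (noise sd = $I_0/20$; the
  interferometric noise case is specified on a dB scale, the movie case as
  a plain ratio). Membrane labelling is emulated only as a geometry (rim
  exclusion is tested with an explicitly brightened ring); photobleaching
  is deliberately not simulated — a `k = 0` configuration provides the
  constant-intensity control arm. Passing the recovery tests therefore
  shows the estimator chain is unbiased under these idealized conditions,
  not that real movies are free of bleaching or focus drift.

Every generator is a pure function of (seed, config): the RNG state is
saved and restored, and identical seeds give bit-identical outputs.

## Numerical and statistical choices

* Noise in the single first-frame $I_0$ propagates as a correlated offset
  through the whole release curve and is the dominant error source of the
  fitted exponent at realistic noise; pooling several vesicles (the
  default) suppresses it. The definition $I_0$ = first frame is kept
  because that is what the fraction means; smoothing $I_0$ would trade
  definition fidelity for variance.
* The Ritger–Peppas fit excludes $t = 0$ and zero fractions (the power law
  is singular in log space there) and every point at or above 0.6.
* FWHM extraction interpolates linearly between samples on both profile
  and waveform paths; a profile without a positive maximum, or whose
  half-maximum is never crossed on one side, is an error, not a guess.
* Degenerate inputs fail loudly with named conditions: `no-carrier` for
  fringe-free images, `unphysical density`/`unphysical pressure` outside
  the Tait branch, `contaminated-background` for a background ROI touching
  a vesicle, `insufficient-data`/`fit-failure` for the release fit,
  `packing error` for impossible movie layouts.

## Problem sizes used in validation

The test and acceptance runs use scaled problem sizes chosen as the
smallest that still exercise every code path meaningfully: 256 × 256
interferograms; 64 × 64 movies with 3 vesicles of 6–10 µm sampled at
0.5 Hz over the full 900 s exposure (the kinetics depend on absolute time,
not frame rate, so slower sampling changes only the point count); 20 seeds
for the multi-seed recovery study; 100 replicates for the fit's Monte
Carlo bias check. The generator defaults themselves (128 × 128 movies,
5 vesicles of 8–15 µm at 2 Hz) describe the experiment being emulated, not
the test sizes.

## Known limitations

* No tomographic (Abel) inversion of the line-of-sight average; pressure
  maps are path-averaged over the 2 mm optical path.
* The 2D unwrapper is sequential, not quality-guided; it assumes smooth
  phase with moderate noise.
* Tracking is greedy nearest-neighbour; it is not meant for dense, mobile
  populations.
* No flow-cytometry file parsing; group statistics accept plain numeric
  vectors.
* Out-of-band hydrophone response is flat-extrapolated, so peak pressures
  of very broadband pulses may be slightly underestimated — matching the
  physical limitation of band-limited calibration data.
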