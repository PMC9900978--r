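---
title: "Simulating and analysing scanless two-photon voltage imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing scanless two-photon voltage imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`voltim` models a voltage-imaging experiment in which a femtosecond laser is
sculpted into soma-sized, temporally focused spots, a genetically encoded
voltage indicator (GEVI) converts membrane potential into fluorescence, and a
fast sCMOS camera records the result. The package covers the three stages of
such an experiment — light sculpting, image formation, and analysis — and is
organised so that every quantity the analysis pipeline reports can be checked
against the known ground truth of the simulation.

This vignette documents the models, their assumptions, the tunable
parameters and the design decisions; the numbered scripts under `analysis/`
run the corresponding experiments.

## 1. Light sculpting

Three modalities produce a ~12 um excitation spot matched to a neuronal soma.
All of them are computed on the spatial-light-modulator (SLM) grid
(600 x 800 pixels, 20 um pitch by default) embedded in a 1024^2 padded array,
and mapped to the sample plane through the relay demagnification
(`demag = 80`, the product of the 400/300 mm Fourier/tube pair and the
300 mm-tube / 5 mm-objective stage), giving a 0.25 um sample-plane pixel and
a ~256 um addressable field.

**Generalized phase contrast (GPC).** `make_gpc_mask()` writes a binary
pi-disk whose radius is the target spot radius times the demagnification;
`gpc_synthesize()` propagates it through the 4f phase-contrast stage: Fourier
transform, a pi shift of the spatial frequencies inside the 60-um-radius
phase-contrast filter (mapped to physical units via the 400 mm transform
lens), and a second transform. The interference of the shifted low-frequency
reference wave with the rest of the beam converts the phase disk into a
quasi-flat-top intensity spot. With the default expanded-beam waist of
3.5 mm at the SLM, the simulated two-photon profile has a 12.0 um lateral
FWHM and delivers 27% of the input power into the disk.

**Expanded-and-cropped Gaussian.** `gaussian_flattop_spot()` models the
low-NA Gaussian alternative analytically: the waist is chosen so the
intensity at the crop edge is `uniformity` times the peak, which fixes the
throughput at `1 - uniformity` (the Gaussian power integral). At the default
uniformity of 0.9 the GPC/Gaussian power-efficiency ratio is ~2.7 —
uniform soma illumination by cropping is roughly three times more expensive
than phase-contrast shaping.

**Computer-generated holography (CGH).** `gs_hologram()` runs an iterative
Gerchberg–Saxton loop treating the SLM as the Fourier conjugate of the
sample. Each iteration replaces the focal amplitude by the energy-scaled
target inside the target support and keeps the computed amplitude elsewhere,
then restores the illumination amplitude at the SLM. Convergence is
monitored as the correlation between reconstruction intensity and target;
it is non-decreasing in practice and reaches > 0.98 for single disks within
30 iterations. `weighted_gs_multiplex()` extends this to up to 100 spots,
rescaling each spot's target by the ratio of mean to achieved amplitude per
iteration (linear weight update; the update exponent is not published for
the reference systems, and the linear choice equalises an 8-spot ring to a
coefficient of variation below 1%).

**Speckle.** Converged single-disk holograms in this idealised,
aberration-free simulation carry low-contrast residual speckle
(`<I^2>/<I>^2` about 1.05–1.15) rather than fully developed speckle;
physical systems sit closer to the fully developed limit of 2. Both regimes
matter: the speckle enhancement is exactly the two-photon efficiency gain at
fixed average power, so the package asserts the *ordering* (CGH above GPC,
everything within [1, 2]) and verifies the fully developed limit separately
with random-phase fields, where `<I^2>/<I>^2 = 2.00` follows from the
negative-exponential intensity statistics.

**Temporal focusing.** `propagate_stack()` performs band-limited
angular-spectrum propagation of a synthesized focal field. The pulse
spectrum is discretised into `spectral_samples` Gaussian-weighted components
(spectral width from the 100 fs transform limit); the grating disperses
component k by an angle `angle_mag * grating_density * dlambda_k`, so away
from focus the components separate laterally by `z * tan(theta_k)`. The
two-photon rate is computed **coherently**: per pixel the pulse is
reconstructed by a discrete Fourier transform across components and the
rate is `sum_t |E(t)|^4`. An incoherent variant (summing component
intensities and squaring) was evaluated first and rejected: it produces
essentially no axial confinement, because time-averaged intensities only
decorrelate on the shear scale, whereas the physical mechanism is the loss
of pulse compression away from the grating-conjugate plane. With the
nominal grating density (600 lines/mm) and relay magnifications, the
simulated axial FWHM of the plane-integrated two-photon signal is ~9 um for
the reduced test geometry and ~20 um for the full-device geometry; because
the effective spectral aperture of the real instrument is not fully
specified, no axial value is asserted numerically — only the orderings
(temporal focusing narrower than none; monotone, saturating improvement
with the number of spectral components; a 1 um bead response narrower than
the plane-integrated spot response), which are robust to this uncertainty.

## 2. The synthetic camera movie

`render_movie()` implements the forward model

```
counts = Poisson( E * (P/Pref)^2 * exc2 * (1 + r * dFF(t)) * B(t) * t_exp )
         * gain + offset + N(0, read_noise)
```

per membrane pixel, with `E` the expression level (photons/pixel/ms), the
quadratic power scaling of two-photon excitation, `exc2` the normalised
two-photon excitation at the pixel, `r` a per-pixel responsivity multiplier,
`dFF` the sensor response and `B` the bleach factor. Somata are membrane
annuli (12 um diameter, 1 um wall by default) at the camera pixel size —
0.1625 um natively; the bundled scenarios use 2x2-binned 0.325 um pixels on
a 44 x 44 grid, which holds one soma and keeps the simulations compact.
Frames integrate the supersampled (0.1 ms) physiology over the exposure
window; the effective frame rate is `1/(exposure + readout)` (1 ms + 0.02 ms
gives the 980 Hz of the reference camera). Frames whose exposure is only
partially illuminated are marked unlit and excluded from dF/F analysis, as
in gated acquisitions.

**Sensor.** The GEVI is linearised: steady-state dF/F is
`sensitivity * dV / 100 mV` with `sensitivity = -0.43` (negative-going),
filtered by first-order on/off kinetics. The kinetic constants are not
published for the indicator; they are free parameters of this model and were
calibrated once so that a 3 ms / 100 mV action-potential surrogate,
frame-integrated, peaks at -30.2 %dF/F0 at 1 kHz and -27.3 at 500 Hz
(`tau_on = 2.1 ms`, `tau_off = 2.5 ms`). The linearisation is used over
-75..+25 mV; real GEVI sensitivity curves are mildly nonlinear, which this
model does not capture.

**Photobleaching.** Double-exponential in *illuminated* time, with rates
scaling as the square of power density (a two-photon process). The fast
pool (default 20% of fluorescence, 1 s time constant at 1.33 mW/um^2) is
recoverable: across each dark interval it refills to at most
`recovery_fraction` (default 0.97) of its original amplitude; the slow pool
(100 s) is permanent. This reproduces the protocol-2 phenomenology: high
photorecovery after 2.5 s dark intervals, photostability decreasing with
power.

**Action potentials** are stylised 3 ms / 100 mV rectangular commands by
default (the waveform used in the cell-culture characterisation protocols);
a triangular alternative is available (`ap_shape = "triangle"`). Real
granule-cell waveforms are not published at the required resolution.

**Spontaneous activity** is an exact-discretisation Ornstein–Uhlenbeck
subthreshold process (default sd 2 mV, 50 ms correlation time) plus Poisson
action potentials with a 20 ms refractory interval — a surrogate with the
right amplitude and timescale, not a biophysical network model.

**Optogenetic actuation.** `simulate_actuation()` draws per-pulse spiking:
probability rises as `(P/saturation)^2` capped at `prob_max = 0.85` (the
photocurrent saturates at 0.02 mW/um^2), latency is Gaussian
(4.3 +- 1.0 ms), and short inter-pulse intervals accumulate a
desensitisation decrement — reproducing the qualitative drop of AP
probability with stimulation frequency; its magnitude is not quantified in
the reference data and the default (15% maximal decrement below 100 ms
intervals) is only meant to produce the trend.

`render_trace()` is the aggregate version of the same model — the summed
membrane photon count per frame — used for long recordings (50 s spike
series, actuation scans) where per-pixel rendering adds nothing to what is
being tested.

## 3. Trace extraction

`initial_segmentation()` thresholds the background-subtracted mean image and
intersects it with an annulus estimated from the radial distribution of the
bright pixels — membrane-labelled somata image as rings, and the annulus
constraint suppresses interior/neighbour pixels. `regression_weight_mask()`
then regresses every pixel on the mean trace of that mask; the slope is the
pixel's weight, negative slopes are clipped (anticorrelated pixels are
background), and the retained support is the upper half of the positive
weights. On heterogeneous cells this roughly halves the pixel count, raises
the extracted -dF/F0 (the weights concentrate on the most responsive
membrane), and leaves the SNR essentially unchanged — the fewer photons are
compensated by higher contrast.

`detrend_dff()` fits a bleach baseline per illumination epoch. Response
frames must not bias the fit, so a first pass fits the bleach model to all
frames and flags frames falling more than 4 noise-sigmas *below* it (the
indicator is negative-going; the monotone first-pass fit cannot chase the
responses), with a +-10 ms margin. The final baseline is a bi-exponential
fit on the retained frames, falling back to a single exponential and then
to a running-percentile filter (with linear interpolation across fully
masked stretches). dF/F is `(F - baseline)/baseline`, defined only on lit
frames; `raw_f` is never modified, so photostability computed before and
after detrending is identical. For photostability the baseline fluorescence
is referenced to the first illuminated frame, the convention used for that
metric; step-response F0 defaults to the pre-step mean.

Step metrics (`-%dF/F0`, empirical SNR) are computed per step with the
amplitude referenced to a baseline interpolated linearly between the
flanking pre/post windows — insensitive to the bleach-fit bridging across
the response — and the noise as the s.d. of contiguous first differences of
dF/F, pooled over baseline and response-plateau frames (plateau differences
rescaled to baseline photon statistics), with >5-MAD outliers clipped. The
first differences make the estimate immune to residual slow structure; the
pooling matters because the r^2 of SNR-versus-power fits is limited by the
precision of this noise estimate.

## 4. Spike detection and scoring

`detect_spikes()` mirrors the template-matching approach used for
fluorescence voltage recordings: (1) candidate peaks of `-dFF` with
topographic prominence of at least 4 noise-sigmas (sigma from the median
absolute first difference); (2) a template averaged from the *most
prominent* 20 peaks; (3) normalised cross-correlation of the template
against the trace — events are correlation maxima above 0.7 that coincide
with a stage-1 peak and whose amplitude exceeds half the median seed
amplitude (floored at 4 sigma), with sub-frame timing from parabolic
interpolation of the correlation peak. The detector is invariant to trace
scaling and offset, returns an empty set (not an error) on featureless
traces, and produces isolated false positives on pure noise at a rate of a
few per hundred seconds at the default thresholds. The matching tolerance
for scoring against reference (electrophysiological) event times is +-5 ms
with greedy one-to-one assignment; greedy matching differs from optimal
assignment only at rates far above the 125 Hz considered here.

`average_trials()` aligns dF/F on stimulus onsets and reports the empirical
SNR of the average as a function of the number of trials; on iid noise it
scales as sqrt(n). The subthreshold scenario normalises each trial by a
linear per-trial baseline fitted to the off-step lit frames — the
within-epoch bleach tilt is identical across trials and would otherwise
never average out.

## 5. Figures of merit

`snr_metrics()` reports the empirical SNR (response amplitude over baseline
s.d.) and the shot-noise SNR `(-dF/F0) * sqrt(F0)` with F0 in detected
photons (counts/gain); the two agree on pure-Poisson data.
`photostability()` is the integral of the baseline trace normalised to
`F0 * n_t`; `photorecovery()` the pre-step fluorescence of each epoch
relative to the first. `fit_power_response()` fits the log-log slope of F0
versus power density (2.00 for unsaturated two-photon excitation) and the
OLS r^2 of SNR versus power (near 1 in the shot-noise limit; the intercept
is left unconstrained and reported). `resolution_curve()` interpolates the
FWHM of a response-versus-displacement scan.

## 6. Study conditions of the bundled scenarios

The scenario defaults are fixed once and define the simulated experiments:

* **Power sweep** (`protocol2-power-sweep`): the five standard power
  densities 0.66–1.55 mW/um^2; ten cells, identical across levels (each
  cell is measured at every power, as in a per-cell power titration);
  expression set so the membrane mask collects ~10^6 expected photons per
  1 ms frame at the lowest power; acquisition at 1 kHz; twelve consecutive
  repetitions of the three-step stimulus per recording (36 illumination
  epochs separated by 50 ms dark gaps). The repetition count is a
  measurement-precision choice: the r^2 of the SNR-power fit is limited by
  the noise-s.d. estimate, whose relative error scales as one over the
  square root of the number of analysed frames, and twelve repeats put that
  error near 0.3% so the fit statistic reflects the physics rather than
  estimator noise.
* **Sub-threshold averaging** (`subthreshold`): 50 trials of 20 ms steps at
  1 kHz under 40 ms strobed illumination; photon budget set so a 100 mV
  step would have a single-trial empirical SNR of ~50 (13,500 photons per
  frame over the mask), which puts a 1 mV step at SNR ~0.4 in single trials
  and above 1 after 25 trials.
* **Train grids** (`fig3-trains`): 10-AP trains at 125 Hz across the five
  power densities and three acquisition rates, with the photon budget
  anchored at 2,178 photons/frame at 1.11 mW/um^2 and 1 kHz (per-AP SNR
  ~14, the single-trial regime of the reference recordings) and scaled by
  the square of power density and linearly with exposure.
* **Resolution scan** (unit-tested): the synthesized 12 um GPC spot scanned
  across a 10 um granule-cell soma with a 2 um Gaussian scattering blur —
  the tissue-slice geometry in which effective resolution is defined; the
  resulting lateral FWHM is ~14 um. Without scattering and with a 12 um
  soma the overlap curve is wider (~18 um) and brittle to the exact
  spot-edge/annulus registration.

## 7. Numerical choices and limitations

* FFTs are centered (origin on the sample at n/2+1); the even-sized SLM
  panel therefore sits half a pixel off the optical axis, which limits
  mirror symmetries to ~1e-4 relative rather than machine precision.
* Angular-spectrum propagation is band-limited at the objective NA and
  zero-padded 2x; energy per plane is conserved to <1% while the field
  stays inside the padded box (large |z| at high NA leaks energy outward,
  which is physical divergence, not a numerical fault).
* FWHMs are linear interpolations of half-maximum crossings through the
  intensity-weighted centroid; profiles that do not bracket the half
  maximum raise errors rather than extrapolate.
* The synthetic data contain no tissue scattering (except the explicit blur
  in the resolution scan), no motion or axial drift, no camera
  fixed-pattern noise, and a linear 16-bit camera. Passing tests therefore
  demonstrate the correctness of the pipeline's computations under
  shot-noise-limited conditions, not robustness to those real-data
  artefacts.
* Determinism: every stochastic stage takes an integer seed and restores
  the RNG state afterwards; identical configurations give bit-identical
  movies, masks and reports.
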