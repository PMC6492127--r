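---
title: "Correcting breathing-induced B0 fluctuations in multi-shot spinal cord MRI"
author: "breathfield package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting breathing-induced B0 fluctuations in multi-shot spinal cord MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathfield)
```

## The problem

Breathing changes the air/tissue distribution of the thorax, and with it the
magnetic susceptibility distribution surrounding the spine. The B0 field
inside the cervical spinal cord therefore oscillates with the respiratory
cycle, most strongly in inferior slices close to the lungs. A time-varying
field offset $f_0(z,t)$ (we carry fields as frequencies in Hz;
$f_0 = \gamma \Delta B_0 / 2\pi$) adds a phase

$$\Delta\phi_0(z, t, t_{RO}) = 2\pi\, f_0(z,t)\, t_{RO}$$

to the acquired MR signal, where $t_{RO}$ is the time since the last RF
excitation. Single-shot acquisitions see this as bulk image shifts, but
*multi-shot* acquisitions — segmented EPI, or multi-echo gradient echo where
each k-space line comes from a different excitation — sample k-space across
many breaths, and the shot-to-shot phase inconsistency turns into ghosting
along the phase-encode axis. At long echo times the accrued phase is large,
so T2\*-weighted imaging is hit hardest: ghosting scatters cord signal over
the image, mimicking faster decay and biasing fitted T2\* low, and in fMRI
time series it inflates the temporal standard deviation and destroys tSNR.

## The correction model

The package implements a retrospective, bellows-based correction:

1. **Calibration.** A fast phase-sensitive FLASH time series of a single
   sagittal slice (volume TR 344 ms, TE 4.08 ms by default) watches the
   field breathe. Per voxel, the phase is unwrapped *over time* (cumulative
   nearest-multiple-of-$2\pi$ correction; no spatial unwrapping), the
   time-averaged phase is subtracted, and the deviation is divided by
   $2\pi\,TE$ to give a field series in Hz. Averaging over the in-cord
   voxels of each axial plane yields $f_0(z, t)$.
2. **Coupling fit.** A linear, per-slice link to the bellows trace $R(t)$ is
   assumed: $\hat f_0(z,t) = R(t)\, c(z)$, with $c(z)$ in Hz per bellows
   unit. $c(z)$ is the scalar least-squares solution
   $\sum_t R f_0 / \sum_t R^2$ over a 30-s window, after automatic
   rejection of frames inconsistent with the model (swallowing produces
   field bursts of up to roughly 40 Hz that are not breathing-linked).
3. **Prediction + demodulation.** During any later scan the synchronized
   trace predicts $\hat f_0(z, t)$ at each excitation; every k-space sample
   is multiplied by $e^{-i\, 2\pi \hat f_0 t_{RO}}$ before reconstruction.
   Magnitudes are untouched by construction; only the corrupting phase is
   removed.
4. **Reconstruction.** Cartesian CG-SENSE (or a plain inverse DFT for fully
   sampled data), followed by RSS echo combination, T2\* mapping and tSNR
   mapping.

The field is treated as spatially homogeneous within each axial slice and
static over each readout train. These are the model's two main idealisations;
in-plane (anterior-posterior) field gradients and intra-readout drift are
out of scope here.

## What the simulator emulates — and what it does not

Because real scanner data cannot ship with a package, every input is
generated by the `simulation` functions with ground truth retained:

- `makePhantom()` — a digital cervical cord: an elliptical tissue "neck"
  containing a CSF annulus around an elliptical cord, replicated over axial
  slices (default 64×64×8, 2×2×3 mm voxels). Cord T2\* defaults to 25 ms,
  inside the 23–35 ms range expected for healthy cord at ultrahigh field
  after correction; CSF (70 ms) and tissue (15 ms) are distinct. The object
  fills only the central FOV so the ghost metric has a clean guard band.
- `makeTrace()` — a quasi-periodic bellows signal: sinusoidal cycles with
  per-cycle period jitter (mean 4.5 s, SD 0.4 s; normal shallow breathing
  spans roughly 3.6–7.7 s periods) and 5% amplitude jitter, sampled at
  50 Hz on an explicit time axis, riding on a constant baseline, with
  sequence trigger marks for synchronization.
- `makeCouplingProfile()` — the breathing-field severity along z, a
  closed-form profile $c(z) = c_0 + g z$ growing toward inferior slices
  (defaults $c_0 = 3$ Hz/unit, $g = 0.4$ Hz/unit/mm, i.e. roughly 3–11 Hz
  peak excursion at unit trace amplitude over a 21-mm stack). No published
  per-subject amplitude exists for this geometry; the defaults are chosen
  to reproduce the qualitative severity of in-vivo ghosting and are
  configuration-exposed, not asserted as physiologic truth.
- `simulateFlash()` / `simulateAcquisition()` — the calibration series and
  the imaging scans (10-echo single-line-per-TR gradient echo; 4-shot
  interleaved EPI with SENSE 2, shot TR 650 ms, echo spacing 1.06 ms, TE
  14 ms). The signal model is the T2\* envelope times the field-induced
  phase; the field is evaluated once per excitation, so demodulating with
  the *true* field must restore the fluctuation-free twin exactly — this
  separates method error from simulator mismatch in the tests. A
  `fieldFun` override and link-noise/swallow-burst terms inject controlled
  model violations. Each simulated set comes with a fluctuation-free twin
  built from the identical noise realization.

Not emulated: bulk and cardiac-cycle motion, CSF pulsation, B1 effects,
steady-state/T1 weighting (folded into proton density — the correction only
touches phase), non-Cartesian trajectories, and real receive-chain noise
correlations. Passing tests therefore demonstrate that the *correction
chain* is implemented correctly and behaves as expected under its own model
class, with controlled violations; they do not certify performance on real
scanner data, where the trace-field link is imperfect in ways the link-noise
term only approximates.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| FLASH volume TR | 0.344 | s | 10–22 samples per breath across normal periods |
| FLASH TE | 0.00408 | s | phase sensitivity of the calibration |
| Fit window | 30 | s | enough breaths for a stable fit; short enough to recalibrate often |
| Outlier threshold `k` | 4 | MAD units | two-pass flagging of swallow-like bursts; <1% false positives under the null |
| Minimum fit frames | 10 | frames | guards against degenerate windows |
| CG iterations / tol | 30 / 1e-9 (1e-6 noisy) | — | noiseless tests are tolerance-limited, not iteration-limited |
| Cord T2\* (phantom) | 25 | ms | mid-range healthy cord value at 7T |
| Coupling profile | 3 + 0.4·z | Hz/unit | monotone growth toward the thorax |

## Numerical choices

- **DFT convention.** All transforms are centered and unitary; DC sits at
  0-based index $\lfloor N/2 \rfloor$ and image energy equals k-space
  energy (pinned by a Parseval test). Phase encoding runs along the second
  image dimension.
- **Sign convention.** A positive field offset accrues phase
  $+2\pi f_0 t_{RO}$ in the signal; correction multiplies by
  $e^{-i 2\pi \hat f_0 t_{RO}}$. Simulator and corrector share one
  package-level sign constant, and a demodulate/remodulate round-trip test
  pins it.
- **Solver.** `cgSense()` uses a conjugate-residual iteration on the
  Jacobi-preconditioned normal operator (preconditioner
  $1/\sqrt{\sum_c |S_c|^2}$, the standard intensity correction). The
  conjugate-residual variant was chosen over textbook CG because it makes
  the tracked residual norm non-increasing on consistent data, which both
  the test suite and the divergence guard (error after three consecutive
  residual increases beyond roundoff) rely on; on these problems it reaches
  machine precision in well under 30 iterations.
- **Trace re-centering.** The measured calibration field has zero temporal
  mean by construction (the time-averaged phase is subtracted), so
  `calibrateField()` re-centers the resampled trace over the same record
  before the no-intercept fit; otherwise a constant residual biases the
  coupling and trips the outlier test on clean data.
- **Out-of-calibration slices** take the nearest calibrated slice's
  coupling (with a warning) rather than linear extrapolation, which is
  unsafe where the profile turns nonlinear near the thorax.
- **Trace interpolation** is linear with edge-holding beyond support (and a
  warning); the prediction error is bounded by
  $\max|R'| \cdot \Delta t \cdot |c(z)|$, which a property test checks.
- **Degenerate inputs.** Zero-variance traces, empty masks, all-excluded
  frames, single-frame unwrapping, all-nonpositive T2\* voxels, zero
  temporal SD and missing container datasets each have a defined, classed
  error or flagged-NA behaviour rather than silent NaNs.
- **Percentiles** use linear interpolation between order statistics
  (`type = 7`), so box-plot summaries are exactly reproducible.

## Design choices where the design was open

- **K-space container.** K-space travels as a single-file R-native
  serialization of three datasets (`data`, `lines`, `meta`) with lossless
  complex round trips and structural validation on read; the line table
  carries explicit 0-based k indices, excitation ids and per-line timing
  rather than assuming an interleave, and the EPI interleave (shot $m$
  acquires $k = R(m + 4r)$) is recorded, not implied. Scanner-vendor raw
  formats are out of scope.
- **Bellows units.** The trace is fitted in raw (mean-removed) bellows
  units; any rescaling of the trace is absorbed by the coupling
  coefficient, so no physical normalisation is attempted.
- **Field evaluation time.** Once per excitation: at the excitation for
  single-line multi-echo GRE, at excitation + TE (echo-train center) for
  EPI — one shared helper (`fieldEventTimes`) serves simulator and
  corrector so oracle correction stays exact.
- **Outlier automation.** In practice swallow-affected frames are excluded
  by eye; the package automates this (provisional fit → MAD flagging →
  refit) because a testable pipeline cannot rely on manual steps.
- **tSNR definition.** Raw mean over sample SD, exactly as defined; an
  optional linear detrend is available but off by default, since the
  definition in use does not specify detrending.
- **EPI reference lines.** The odd/even (reversed-polarity) phase
  discrepancy is corrected with externally supplied constant+linear
  coefficients per slice, applied in hybrid (x, k$_y$) space — matching a
  phantom-calibrated correction. The operation is not idempotent, so a
  container flag refuses double application.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at 64×64 in-plane
matrices with 8 slices (1 inferior slice for the EPI time series), 10-echo
gradient echo, 120-volume 4-shot EPI, 100 calibration noise realizations
and 20 EPI seeds. These sizes were chosen so the full suite demonstrates
every claim — exactness at machine precision, recovery rates, bias
directions and monotonicity — on a workstation in minutes; all generators
scale to larger matrices through their arguments.

## A compact worked example

```{r example}
ph  <- makePhantom()
tr  <- syncTrace(makeTrace(75, periodSdS = 0, seed = 3))
cp  <- makeCouplingProfile(zMm(ph)); cp <- cp * 10 / max(cp)
mdl <- makeBreathingModel(cp)

# calibrate from a simulated FLASH series at image SNR 20
fl  <- simulateFlash(ph, tr, mdl, durationS = 60, noiseSd = 0.05, seed = 2)
cal <- calibrateField(fl$series, fl$mask, tr)
round(couplingHz(cal), 2)

# acquire, correct, reconstruct, quantify
sim <- simulateAcquisition(ph, megreSeq(), tr, mdl, seed = 4)
cor <- correctAcquisition(sim$kspace, cal, tr)
tes <- echoTimesMs(sim$kspace)
t2u <- fitT2Star(Mod(imageData(fftRecon(sim$kspace))), tes, cordMask(ph))
t2c <- fitT2Star(Mod(imageData(fftRecon(cor))), tes, cordMask(ph))
c(uncorrected = summarizeRoi(mapValues(t2u), validMask(t2u))$median,
  corrected   = summarizeRoi(mapValues(t2c), validMask(t2c))$median)
```

The uncorrected median understates the 25-ms ground truth; the corrected
median recovers it.

## Known limitations

- The linear trace-field link degrades for deep or irregular breathing;
  the link-noise term models this only as white Gaussian violation.
- In-plane field gradients and 3D acquisitions are not corrected.
- The T2\* fit is monoexponential on magnitudes with no offset; the Rician
  noise floor biases long-TE fits slightly and is measured, not corrected.
- The simulator evaluates the phantom on the reconstruction grid (an
  accepted inverse crime): gridding fidelity is not what these tests probe.
- Coil sensitivities are known to the reconstruction; autocalibrated
  estimation is out of scope.
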