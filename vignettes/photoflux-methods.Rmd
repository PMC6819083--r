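---
title: "photoflux: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{photoflux: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoflux)
```

This vignette explains the science behind each stage of the pipeline, the
assumptions it rests on, and the decisions taken where the underlying
procedures are conventionally under-specified. The companion README shows
the user-facing workflow; here the focus is on *why* the code does what it
does.

## The acquisition model

A lock-in photometry rig modulates the 490 nm (sensor) and 405 nm
(isosbestic) LEDs at distinct carrier frequencies — 211 Hz and 531 Hz by
default — and sums both fluorescence returns on one photodetector. The
synthetic generator reproduces this acquisition:

$$v(t) = \varepsilon(t) + b(t)\,\big[A_{490}\,(1 + \Delta F/F(t) + m(t))\,
\sin(2\pi f_{490} t) + A_{405}\,(1 + m(t))\,\sin(2\pi f_{405} t)\big]$$

with white detector noise $\varepsilon$, shared multiplicative bleaching
$b(t)$, and a shared fractional motion artifact $m(t)$. Three physical
assumptions matter:

* **Motion is common-mode and fractional.** Fiber bending and tissue
  movement change the coupling efficiency, which scales both excitation
  paths identically. This is exactly the assumption that justifies
  isosbestic correction; if motion were wavelength-dependent the 405 nm
  regression could not cancel it.
* **Bleaching is multiplicative and shared.** A single exponential with a
  1200 s time constant by default (a second, faster component can be mixed
  in via `bleach_tau2_s`/`bleach_frac2` to emulate the early fast decay of
  freshly illuminated tissue).
* **The dopamine signal rides only on the 490 nm channel.** The isosbestic
  wavelength is ligand-independent by construction of the sensor.

### Generator parameters and their defaults

| parameter | default | rationale |
|---|---|---|
| `fs_raw` | 6112 Hz | 16 × 382, so decimation to the 382 Hz output rate is an exact integer factor and introduces no resampling interpolation |
| `fs_out` | 382 Hz | the digitization rate of the emulated acquisition system |
| `carrier_490_hz`, `carrier_405_hz` | 211, 531 Hz | the emulated rig's LED modulation frequencies; both far below the raw Nyquist rate, separated by 320 Hz |
| `transient_rate_hz` | 0.5 /s | the spontaneous dopamine transient rate reported for wild-type ventral-striatal recordings |
| `transient_amp` | 0.05 ΔF/F | a typical clear spontaneous dLight transient (a few percent) |
| `transient_tau_rise_s`, `transient_tau_decay_s` | 0.05 s, 0.5 s | difference-of-exponentials kernel chosen to match sub-second dopamine sensor transients; the event FWHM (~0.4 s) lands in the observed range |
| `bleach_tau_s` | 1200 s | slow photobleaching at modest LED power: ~22% loss over a 5-min epoch |
| `motion_amp` | 0.01 | 1% RMS fractional coupling fluctuation, band-limited below 2 Hz (body movement is slow relative to transients) |
| `noise_sd` | 0.004 V | derived from the femtowatt photoreceiver class used in these rigs: NEP ≈ 7 fW/√Hz at 10¹⁰ V/W gain over the ~3 kHz raw band, i.e. ~4 mV RMS on a ~1 V carrier. After demodulation this leaves ≈ 0.1% ΔF/F noise, so default transients have peak SNR of a few tens |
| `amp_490`, `amp_405` | 1.0, 0.7 V | arbitrary; LED power and detector gain are rig-specific and the pipeline is scale-invariant past the ΔF/F step. They are documented, not fitted |

Event times are a homogeneous Poisson process. Real transient trains show
some refractoriness; the Poisson choice is deliberate (it is the simplest
null model with the right rate) and has one visible consequence discussed
under *Known limitations*.

All randomness derives from one user seed, fanned out deterministically to
per-component sub-streams, so identical configurations are bit-identical.

## Demodulation and filtering

Each carrier is recovered by sine-reference quadrature lock-in:
$a(t) = 2\sqrt{LP[v\sin(2\pi f_c t)]^2 + LP[v\cos(2\pi f_c t)]^2}$. The
factor 2 makes the output equal the carrier *amplitude* regardless of the
carrier phase — hardware lock-ins differ in this convention, so it is
stated explicitly. A square-wave reference would also have worked; sine
reference was chosen because it rejects the other carrier's odd harmonics
better at this frequency spacing.

The low-pass `LP` is the same filter used everywhere in the package: a
second-order Butterworth applied forward and backward. Zero-phase
filtering matters because transient *timing* is an output; a causal filter
would delay peaks by a bandwidth-dependent lag. The two-pass amplitude
response is the squared single-pass response: DC gain exactly 1, gain
exactly 1/2 at the cutoff. The default 25 Hz cutoff matches the final
signal bandwidth of the emulated acquisition chain.

Numerical edge handling: each pass uses odd (point-reflected) padding of
three filter lengths plus steady-state initial conditions at the edge
value, so constants pass through exactly and startup transients are
strongly suppressed. Residual edge effects are handled one level up:
`demodulate_session()` flags the first and last second as
edge-contaminated, and the transient detector excludes flagged samples
from peaks and from the rate denominator.

Decimation anti-aliases at 0.4 × the output rate (fourth-order, zero
phase) and then keeps every k-th sample; non-integer rate ratios are
rejected rather than resampled.

## Isosbestic correction and normalization

The 405 nm channel is regressed onto the 490 nm channel by ordinary least
squares *over the entire session* — a single fit, not windowed. Windowed
or robust variants exist in the literature, but a single OLS fit is the
convention this pipeline follows, and the synthetic suite shows it
recovers ground truth well when the session is long enough for bleaching
to give the regression leverage (recovery correlation ≈ 0.99 on 300–600 s
sessions; short 1-min segments leave the fit poorly conditioned).

$\Delta F/F = (F_{490} - \hat F_{405}) / \hat F_{405}$ then cancels the
shared multiplicative structure. No additional detrending is applied — the
isosbestic division is the only baseline model.

The robust z-score is the literal $(x - \mathrm{median}(x))/\mathrm{MAD}(x)$
with **no** 1.4826 Gaussian consistency factor: the convention here
follows the formula as used in the photometry literature, and the
`consistent` flag enables the scaled variant for users who want
Gaussian-comparable units. Consequently "2 z" means two MAD units, not two
standard deviations (≈ 1.35 SD under Gaussian noise).

## Transient detection

Peaks are strict local maxima (plateau ties resolve to the earliest
sample) whose **topographic prominence** reaches the threshold — 2 z by
default. Prominence, not raw height, is thresholded so that a small bump
riding on a tall transient's shoulder does not count as a second event
merely for being high. Prominence is computed exactly on the compressed
sequence of alternating extrema, which is equivalent to the textbook
definition on raw samples (the test suite checks this against a
brute-force oracle) and fast on long sessions.

Detected peaks closer than `min_separation_s` (default 0.2 s) keep the
larger, then earlier, peak. FWHM is measured at half-*prominence* by
linear interpolation of the flank crossings; half-height is available via
`fwhm_at`, and on the near-zero baselines produced by robust
normalization the two coincide closely. Both height and prominence are
reported per event, since published "amplitude" metrics are ambiguous
between the two.

The session rate is `count / analyzed duration`, the analyzed duration
excluding edge-flagged seconds.

### Scoring against ground truth

`match_transients()` scores detections with tolerance-window matching
(0.25 s): a detection is correct if a true event lies within tolerance,
and an event is recalled if a detection lies within tolerance. Matching is
deliberately not forced one-to-one: with Poisson event times and a 0.5 s
decay kernel, ~13% of events arrive closer than the kernel's resolvable
separation (~0.3 s) and physically merge into a single peak, which no
detector operating on the trace can split. One-to-one matching would cap
recall near 0.87 as a property of the *generator*, not the detector.

The same pile-up gives the detected **rate** an intrinsic negative bias of
roughly 8–12% relative to the generating rate (merged pairs count once).
This is a real property of peak-counted event rates — published rates are
detected rates and carry the same bias with respect to the underlying
point process — and it is left visible rather than corrected away.

## Peri-event analysis

Trial matrices are exact sample slices (no resampling) around each labeled
event; windows that would overrun the trace drop the trial with a report
rather than padding silently. Features use time-anchored windows, all
configurable, with defaults chosen from the canonical aversive-US
waveform (an initial positive transient, a 1–2 s signed anti-peak, then a
broad rebound): CS peak over [0, 2] s after CS onset, US peak over [0, 1] s
after the US, anti-peak over [0.5, 2.5] s, rebound AUC (trapezoidal) over
[2, 8] s. Heatmaps and features use the session-level robust z — sessions,
not trials, are the normalization unit.

In appetitive (pavlovian) sessions the effective US time is the start of
the first lick bout at or after reward presentation, because consumption —
not the pump command — is what the dopamine response locks to.

## Behavioral metrics

The lick-bout rule "exceeds five licks per second, at least 3 s removed
from a previous bout" is operationalized as: a bout starts at the first
lick of any run with ≥ 5 licks inside a sliding 1 s window, ends after 3 s
of silence, and bouts closer than 3 s merge. The window width is a
parameter; 1 s is the natural scale for a rate quoted per second.
Anticipatory licks are licks in [CS onset, US delivery) — the obvious
reading of a term the source conventions leave undefined. Learning rate is
the OLS slope of CS lick counts against trial (or session) index; freezing
acquisition is the OLS slope over trials 1–7 with plateau means over
trials 8–15 (both split points configurable).

## Morphometry

Sholl analysis counts parent→child segments whose endpoint distances from
the soma (the root node's coordinates) straddle each shell radius:
$\min(d) < r \le \max(d)$. A segment whose endpoint lands exactly on a
shell counts as crossing it from below and is not re-counted by the next
segment — a documented boundary rule, applied with a 10⁻⁹ relative slack
so that geometrically exact constructions are not lost to floating-point
rounding. Distances are 3-D Euclidean; `planar = TRUE` serves 2-D traces.
Soma contours yield area by the shoelace formula and major/minor axes as
the equivalent-ellipse diameters $4\sqrt{\lambda}$ from the polygon's
second-order area moments.

## Group statistics

Summary-based t tests reconstruct group SDs as $SEM\sqrt{n}$; printed
summaries are rounded, which propagates roughly ±0.02 into reconstructed
t values — agreement tighter than that is not meaningful. The
Benjamini–Krieger–Yekutieli procedure implemented is the two-stage linear
step-up: stage 1 runs Benjamini–Hochberg at $q' = q/(1+q)$, estimates the
null count $\hat m_0 = m - r_1$, and stage 2 reruns BH at $q' m/\hat m_0$.
It is defined by its rejection set, so the function returns flags, not
adjusted p-values. KS, Pearson, and raw-data t tests delegate to the
standard stats implementations behind tidy one-row-tibble surfaces.

## What the synthetic data does and does not show

The generator covers: amplitude-modulated two-channel acquisition, shared
bleaching and motion, Poisson transients with a fixed kernel, trial
schedules with uniform 75–105 s ITIs (10 s CS; US at +7 s for reward, a
1 s US at CS offset for fear), jittered lick trains inside declared bouts,
and exactly-known toy morphologies. Passing the recovery suites therefore
demonstrates that the *pipeline* is correct and self-consistent.

It does **not** demonstrate performance on real recordings, which add:
wavelength-dependent (non-common-mode) motion, hemodynamic artifacts,
state-dependent baseline dynamics that inflate the MAD, variable kernel
shapes, non-Poisson event statistics, and electrical interference. The
detection operating point in particular (2 z) sits much closer to the
noise floor on real data, where trace variability is signal-dominated,
than on the synthetic flat-baseline model.

## Problem sizes

The validation suites run on sizes chosen to keep the full check suite in
the one-minute range while leaving estimates stable: a 600 s session at
6112 Hz raw (≈ 3.7 M samples) for ground-truth recovery, 300 s sessions
for module-level recovery checks, 5 000 replicates × 20 p-values for the
null FDR simulation, 200 random sample pairs for the KS oracle, and 100
random trees for the Sholl oracle.

## Known limitations

* The TTL alignment model is a single shared pulse; clock *drift*
  correction from repeated pulses is not implemented.
* The reference fit assumes one linear relation per session; sessions with
  a mid-recording coupling change (e.g. a bumped patch cord) should be
  split before processing.
* Detected rates inherit the pile-up bias described above; at 0.5
  events/s with a 0.5 s kernel, expect detected rates ~10% below the
  underlying point-process rate.
* Freezing scores are consumed from externally scored tables; no video
  analysis is included.
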