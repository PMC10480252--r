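---
title: "The virtual aortic-stenosis flow phantom: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The virtual aortic-stenosis flow phantom: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowphantom)
```

## Why a virtual phantom

Transvalvular pressure drops are the working currency of aortic-stenosis
grading, but the three quantities that clinicians and physiologists call
"the gradient" are not the same number. The *instantaneous peak* drop is
the largest same-instant difference between the pressure before the valve
and the spatial minimum in the jet; the *net* drop is what remains after
downstream pressure recovery and is the true extra afterload on the
ventricle; the *peak-to-peak* drop compares the temporal maxima of the
upstream and downstream pressures, which occur at different instants.
Bench studies with a mock circulatory loop — a pump, a valve in a straight
compliant tube, and an array of wall pressure ports — are the standard way
to study how reliably each metric can be measured. `flowphantom`
reimplements such a bench in software: a parametric 1-D pressure-field
generator with known ground truth, the full signal pipeline used to
extract the three metrics, and the test–retest harness used to quantify
their reproducibility. Everything a physical rig makes expensive —
repeating a protocol under a fresh seed, toggling wave reflection on and
off, comparing an extracted value against truth — is a function call.

## The generator

### Geometry and flow

The phantom is a 32-mm internal-diameter tube with eight pressure ports at
−30, +15, +30, +50, +75, +100, +200 and +500 mm from the valve plane (one
upstream reference, two in the jet, five through and past the recovery
zone). The working fluid is a blood-mimicking water–glycerol mixture
(density 1.119 g/cm³, viscosity 4.83·10⁻³ Pa·s). The pump runs at
75 bpm with peak flows of 100–250 ml/s, either pulsatile or constant.

The pulsatile waveform is a raised-cosine upstroke over the first 30 % of
systole followed by a raised-cosine decay, with systole occupying 35 % of
the cycle and zero diastolic flow (a non-return valve clips reverse flow).
An asymmetric systole was a deliberate choice over a symmetric half-period
cosine: physiological aortic flow peaks early in systole, and the early
peak also places the peak-drop instant *before* the round-trip delay of
any reflected wave reaching ports 1–7 (see below). Both fractions are
configurable.

### Pressure field

At each instant the vena-contracta drop is

$$\Delta P_{vc}(t) = 4\,v(t)^2 \;+\; K\,\rho\,L_{\mathrm{eff}}\,\frac{dv}{dt},
\qquad v = Q/\mathrm{EOA},$$

the clinical simplified-Bernoulli term plus an unsteady inertial term
(default $K = 1$, $L_{\mathrm{eff}} = 30$ mm; $K = 0$ gives the
quasi-steady regime). The inertial term is why pulsatile runs show larger
peak drops than constant-flow runs at the same peak flow: the transient
jet never settles into the steady, more efficient flow configuration.

Axially, the drop rises from zero at the valve plane along a smooth sin²
ramp, holds at $\Delta P_{vc}$ across a jet core (vena contracta
+25 mm ± 13 mm, so that both jet ports sample the full drop even when
remounting jitters the jet by a few millimetres), and then relaxes
exponentially (length scale 35 mm) toward the net drop

$$\Delta P_{net}(t) = \Delta P_{vc}(t)\,\bigl(1 - 2r(1-r)\,\eta\bigr),
\qquad r = \mathrm{EOA}/A,$$

the standard orifice pressure-recovery relation, scaled by a recovery
efficiency $\eta$ (default 1) that represents how completely the jet's
kinetic energy is actually reconverted — jet angulation, wall deformation
and flow oscillation all degrade it in practice. With the default
recovery length, recovery is ≥ 99 % complete at the +200 mm port, which
is why that port (channel 7) serves as the "after recovery" reference.
All ports ride on a common pump pulse (40 mmHg at 250 ml/s, scaling with
flow) above a 60 mmHg diastolic baseline; without it the peak-to-peak
metric would have no temporal maxima to compare.

The default valve EOA of 1.018 cm² is the healthy-valve calibration: at
250 ml/s it gives v = 2.46 m/s and a 24.1 mmHg Bernoulli drop, just below
the 25 mmHg (2.5 m/s) threshold that supports a stenosis diagnosis. Note
a deliberate inconsistency kept from the physical reference: with the
32-mm tube this EOA implies r = 0.127 and a net/peak ratio of 0.78,
whereas the observed net-vs-peak regression regime (slope ≈ 0.63)
corresponds to r = 0.245. A 1-D orifice law cannot satisfy both at once;
analyses that target the 0.63 regime set `set_orifice_ratio(cfg, 0.245)`
explicitly.

### Wave reflection

The tube end is an impedance step that reflects a fraction Γ (default
0.4) of the forward wave. The forward wave is treated as spatially
instantaneous (long-wavelength limit); the reflected component at port
$x$ is the port's AC pressure delayed by the round trip
$2(\mathrm{site}-x)/c$ (default site 600 mm, $c$ = 8 m/s) and scaled by
Γ. The delay is implemented as a zero-padded shift: recordings start at a
cycle onset, so the pre-arrival history falls in diastole where the AC
pressure vanishes, making this exactly the periodic steady state.
Constant flow carries no travelling transient, so reflection leaves it
unchanged.

This geometry produces the central mechanism the package exists to
demonstrate. The peak-drop instant t\* falls at ~0.06–0.08 s (early
systole); the round-trip delays of ports 1–7 all exceed it, so at t\* the
reflected wave has not yet arrived anywhere that the instantaneous
metrics look — they are structurally immune to Γ. The temporal *maxima*
of the port pressures, however, occur later, where the reflected wave
augments and time-shifts them; the peak-to-peak metric is built from
exactly those maxima. Toggling Γ from 0 to 0.3 on a noise-free phantom
moves the peak-to-peak drop by ~16 % while moving peak and net by less
than 0.1 %. Port 8 (+500 mm) *is* reached quickly by the reflection —
which is why channel 7, not 8, is the recovery reference.

### Noise

Four components, each calibrated as a raw-signal standard deviation and
each zeroable:

* broadband white sensor noise (0.3 mmHg) on every channel;
* jet turbulence and leaflet flutter: high-frequency noise (differenced
  white noise, so its power sits far above the cardiac band) with sd
  $1.5\,e^{-|x - x_{vc}|/30\,\mathrm{mm}}\,(v/2.5\,\mathrm{m\,s^{-1}})^2$ mmHg,
  tripled under constant flow, where turbulence has time to develop
  fully — the jet ports (channels 2–3) are visibly the noisiest;
* a slow coherent oscillation of the recovered pressure (relative
  amplitude 0.5, correlation time 0.8 s): the jet-breakdown region flaps
  on sub-Hz timescales, modulating how much pressure the recovery-zone
  ports see. Because its correlation time is comparable to the beat,
  ensemble averaging suppresses it only partially — this is the dominant
  reason the net drop is measurably noisier than the jet-core peak drop;
* a pump artifact (1 mmHg, 120 Hz bursts at peak dQ/dt and peak flow,
  identical on all channels, pulsatile only).

### Handling perturbations and the two-day design

The test–retest protocol is 4 handling conditions × 2 sessions × 8 flow
regimens = 64 experiments. Condition 1 is untouched; condition 2 (purge,
refill, reposition tubing) jitters the afterload (baseline pressure and Γ,
±5 %) and the distal coupling — pulse amplitude, wave speed, reflection
site (±25 %; trapped air and tubing position change these strongly, and
they are precisely the quantities a bench protocol cannot lock down);
condition 3 (remount the same valve) additionally jitters the
vena-contracta position (±3 mm), the EOA (±2 %) and the recovery
efficiency (±15 %); condition 4 (mount a sister valve) adds a ±3 %
manufacturing EOA offset. Session B multiplies the EOA by 0.96,
emulating a small day-2 increase in obstruction; whether such a bias
arises from leaflet-surface change or from a transducer zeroing error is
not resolvable from pressures alone, so both variants are implemented
(`session_b_mode = "obstruction"` or `"zeroing"`, the latter an offset on
the reference transducer only). Each condition–session combination is
perturbed once and then runs all eight regimens, as a physical protocol
would; all jitters draw from a fixed-order substream of one master seed.

The perturbation magnitudes for the package's own parameters (coupling,
recovery efficiency, recovery oscillation) were calibrated once so that
the harness lands in the reproducibility regime reported for the physical
bench — session r² around 0.99 for the peak, mid-0.9s for the net and
0.6–0.9 for the peak-to-peak drop — and then frozen. They are stand-ins:
no physical measurement of these jitters exists.

## The pipeline

1. **Filtering.** Zero-phase (forward–backward) low-pass Butterworth,
   default order 4, cutoff 50 Hz — high enough to keep ~40 cardiac
   harmonics, low enough to remove turbulence noise. Zero-phase matters
   because the peak instant is a timing measurement. The implementation
   demeans and odd-reflects each trace before `signal::filtfilt`, because
   forward–backward filtering from zero state would otherwise leave a
   settle-in transient at physiological DC levels. Filtering precedes
   segmentation and averaging: pump artifacts are asynchronous with the
   cycle anchor and would otherwise bias it.
2. **Segmentation.** Cycles are cut at the known pump period (60/75 s),
   anchored at the first upward crossing of 25 % of the reference
   channel's dynamic range; only complete cycles are kept. A 50,000-sample
   acquisition at 10 kHz spans 6.25 cycles and yields 6.
3. **Ensemble averaging.** Pointwise mean per channel across cycles; the
   across-cycle variance is reported per channel as the beat-to-beat
   reproducibility readout.
4. **Metric extraction.** t\* is the instant maximising channel 1 −
   channel 7 (ties to the earliest instant). The eight port pressures at
   t\* are interpolated along the tube with a modified-Akima piecewise
   cubic Hermite interpolant, and the *peak drop* is channel 1 minus the
   interpolant's minimum, located on a 1-mm grid (grid search rather than
   root-finding: robust to the interpolant's piecewise structure, and a
   1-mm grid is far below the sensor spacing). The *net drop* is
   channel 1 − channel 7 at t\*; the *peak-to-peak drop* is the absolute
   difference of the two channels' temporal maxima, computed on the
   averaged tracing by default (`p2p_on_raw` switches to the filtered raw
   traces). Constant-flow recordings have no cycles: each channel is
   time-averaged over the whole recording and the same spatial extraction
   is applied; peak-to-peak is reported `NA`.

Two readings of the extraction are defensible: find t\* first and then
take the spatial minimum (the default, matching the two-step procedure of
identifying the peak instant from channels 1/7 and then reconstructing
the longitudinal profile at that instant), or maximise the spatial-minimum
drop over every instant (`time_search = "all-instants"`). On clean
recordings they agree to well under 1 %.

The modified-Akima slopes are computed by hand (no installed R package
provides them) and evaluated through `stats::splinefunH`; the
implementation reproduces an independent reference implementation to
10⁻¹⁰ in the test suite. Modified Akima was chosen over a plain cubic
spline for the same reason bench analyses choose it: next to the
near-flat jet-core minimum a spline overshoots, whereas the
averaged-magnitude Akima weights stay put; node exactness and linear
reproduction are tested properties.

## Statistics

Between-session agreement is ordinary least squares of session B on
session A pooled across conditions and flow rates within a mode (16
pairs), with a t-based 95 % CI on the slope, plus Bland–Altman bias,
sample-sd of the differences, 1.96-sd limits of agreement, and percent
bias relative to the grand mean of pairwise means. Metric-to-metric
relations are OLS pooled across runs of a mode. Constant-mode
peak-to-peak values are undefined and excluded rather than imputed. Both
statistics are cross-checked in the tests against brute-force
normal-equation oracles at 10⁻¹⁰.

## What the simulations do and do not show

The generator reproduces the *structure* the analysis assumes: a
recoverable Bernoulli drop with known truth, reflection-confounded distal
maxima, spatially localised turbulence noise, handling-dependent
perturbations and a day-2 bias. Passing tests therefore demonstrate that
the pipeline measures what it claims to measure under that structure, at
the study's flow conditions and sample sizes. They do not validate the
model against a physical rig: the pump waveform, compliance behaviour,
perturbation magnitudes and the upstream pulse are physiological
stand-ins, not calibrated measurements; the 1-D field has no
Navier–Stokes content, no compliant-wall mechanics and no anatomical
geometry. Conclusions about *which metric is robust and why* transfer;
absolute numbers beyond the calibrated Bernoulli regime do not.

## Numerical and scale choices

Default acquisitions are 50,000 samples at 10 kHz (5 s, 6 complete
cycles). Replicate studies (the reproducibility harness, the analysis
scripts) use 4 kHz × 20,000 samples — the same 6 complete cycles at a
quarter of the cost; a 64-run harness takes roughly two seconds. Seeds
control every stochastic element: a recording's `rng_seed` fixes its
noise; a design's master seed fixes the perturbation and noise substreams
of all 64 runs; identical seeds give bit-identical output. Recordings
round-trip through CSV at 17 significant digits (bit-exact for doubles),
with acquisition metadata in a YAML sidecar, and every analysis script
writes a JSON manifest with MD5 hashes sufficient to re-run it.
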