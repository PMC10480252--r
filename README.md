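# flowphantom

A virtual mock circulatory loop for studying how reliably transvalvular
pressure-drop metrics can be measured in aortic stenosis.

Bench studies of aortic-stenosis haemodynamics mount a valve in a
straight "aorta" instrumented with wall pressure ports, drive it with a
pulsatile pump, and extract three competing severity metrics from the
multi-channel pressure recordings:

* **instantaneous peak drop** — at the instant *t\** of maximal
  upstream-to-recovered pressure difference, the upstream pressure minus
  the spatial minimum of the interpolated longitudinal pressure profile
  (the clinical Doppler analogue: ΔP ≈ 4 v² mmHg, v in m/s);
* **net drop** — upstream minus fully recovered pressure at *t\**; after
  pressure recovery this is the true extra ventricular afterload, and for
  an orifice of area ratio r = EOA/A it is the fraction 1 − 2r(1 − r) of
  the peak drop;
* **peak-to-peak drop** — the difference of the *temporal maxima* of the
  upstream and recovered pressures, which occur at different instants.

`flowphantom` rebuilds that bench in software. A parametric 1-D generator
produces 8-channel recordings with known ground truth — pulsatile or
constant pump output (75 bpm, 100–250 ml/s), a vena-contracta Bernoulli
drop with an unsteady inertial term, exponential pressure recovery,
backward wave reflection from the tube end, distance-dependent turbulence
noise, pump artifacts, and the handling perturbations of a 4-condition ×
2-session × 8-regimen test–retest protocol. The companion pipeline
implements the extraction procedure (zero-phase Butterworth filtering,
cardiac-cycle ensemble averaging, modified-Akima spatial interpolation)
and the agreement statistics (OLS regression with r² and slope CI,
Bland–Altman bias and limits of agreement).

The package exists to make one mechanism concrete: the instantaneous peak
and net drops are measured at a single instant early in systole, before
the reflected wave arrives anywhere upstream of the last port, while the
peak-to-peak drop is built from temporal maxima that wave reflection
augments and time-shifts. Peak and net are therefore reproducible
valve-intrinsic measurements; peak-to-peak is partly ruled by the
vascular coupling and is not.

## Worked example

Simulate the default healthy-valve phantom (EOA 1.018 cm², 10 kHz,
50,000 samples) at the highest flow rate and run the full pipeline:

```r
library(flowphantom)

cfg <- phantom_config()
rec <- simulate_recording(cfg, flow_condition("pulsatile", 250))
rec
#> <sensor_recording> 50000 samples x 8 channels @ 10000 Hz
#> <flow_condition> pulsatile, peak 250 ml/s @ 75 bpm
#>   ground truth: peak 26.82 mmHg, net 20.89 mmHg at t = 4.072 s

analyze_recording(rec)
#> <pressure_drop_metrics>
#>   peak drop:         27.060 mmHg at +24 mm, t* = 0.0429 s
#>   net drop:          21.643 mmHg (ch1 - ch7)
#>   peak-to-peak drop: 12.570 mmHg
```

The pipeline recovers the generator's ground truth (26.82 / 20.89 mmHg)
to about 1 % and 4 % under the default noise model, locates the peak at
+24 mm — between the two jet ports, where the vena contracta (+25 mm)
actually sits — and reports the peak-to-peak value that wave reflection
has pushed well below the net drop. At 250 ml/s the jet velocity is
2.46 m/s, so the quasi-steady drop (24.1 mmHg) stays just under the
25 mmHg (2.5 m/s) stenosis threshold: a healthy valve; the pulsatile
excess over 24.1 is the inertial (flow-acceleration) contribution.

The analysis workflow lives in `analysis/` and runs in order:

```sh
Rscript analysis/01_simulate_phantom.R    # 8 reference acquisitions + ground truth
Rscript analysis/02_extract_metrics.R     # pipeline metrics vs truth -> results/metrics.csv
Rscript analysis/03_reproducibility.R     # 64-run test-retest harness, r2 + Bland-Altman
Rscript analysis/04_metric_relations.R    # how the three metrics relate to each other
```

Step 3 prints the study's key finding in one line, e.g. (seed 1):

```
Pulsatile session agreement: r2(peak) = 1.000 >= r2(net) = 0.952 > r2(p2p) = 0.588: TRUE
All biases positive (day-2 obstruction increase): TRUE
```

See `vignettes/virtual-phantom-methods.Rmd` for the model, its
assumptions, the parameter table and the design decisions.

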