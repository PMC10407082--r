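---
title: "An in-silico test bench for LVAD suction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An in-silico test bench for LVAD suction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suctionsim)
```

## What the package models

Continuous-flow left ventricular assist devices (LVADs) run at constant
speed and are nearly insensitive to preload. When the supported
ventricle is underfilled — for instance during hypovolemia — the pump
keeps drawing blood, left ventricular pressure falls below zero, and
the ventricular wall collapses over the inflow cannula. These *suction
events* can trigger arrhythmias, thrombosis and pump stoppage, and are
the reason physiological pump controllers are being developed.

`suctionsim` is a software test bench for this phenomenon. It couples
three sub-models into one set of ordinary differential equations,
integrated together by a compiled fixed-step solver:

1. **A closed-loop lumped-parameter circulation.** Four time-varying
   elastance chambers (LV, RV and two passive, constant-elastance
   atria), four diode-resistance valves, and two RC vascular beds
   (systemic and pulmonary, each with an arterial compliance, a
   peripheral resistance and a venous reservoir). Total blood volume is
   conserved exactly: the eight compartment volumes are the state
   variables and their derivatives sum to zero by construction.
2. **An HVAD-like rotary pump.** A quadratic head-flow-speed
   characteristic `dP = a0*w^2 + a1*w*q + a2*q|q|`, blood inertance in
   the cannulae, impeller rotational dynamics loaded by a hydraulic
   torque proportional to flow, a PI constant-speed controller with
   anti-windup, and a static current/speed flow estimator that is exact
   in torque equilibrium.
3. **A collapsible apex.** The pump draws from the LV apex through a
   resistance controlled by a collapse fraction; the collapse fraction
   relaxes toward a sigmoid target in LV pressure centred at the
   0 mmHg suction threshold.

On top of the simulator sit the experiment protocols (baseline runs,
hypovolemia ramps, a speed sweep), and the beat-level detection
pipeline: beat segmentation from the 50-Hz estimated pump flow, three
suction features per beat, and a 3-split decision tree.

## Chamber model

Each ventricle blends a linear end-systolic and an exponential
end-diastolic pressure-volume relation with a normalized double-Hill
activation `a(t)`:

$$P(V, t) = a(t)\,E_{es}(V - V_0) + (1 - a(t))\,S\,(e^{k(V-V_0)} - 1)$$

Diastolic stiffness is anchored through V30, the volume at which
end-diastolic pressure reaches 30 mmHg, so `k = log(1 + 30/S)/(V30 -
V0)` (see `edpvr_k()`). The two shipped phenotypes are the published
archetypes: a dilated cardiomyopathy (DCM: `Ees` 0.4 mmHg/mL, V30
210 mL, large compliant ventricle) and a restrictive cardiomyopathy
(RCM: `Ees` 3.3 mmHg/mL, V30 95 mL, small stiff ventricle), both at
78 bpm and supported at 2,800 rpm.

Only the phenotype-defining parameters are published; every other
parameter of the loop (vascular resistances and compliances, right
heart, atria, unstressed volumes, total blood volume) is a free
calibration parameter. They were fitted once so that the closed-loop
steady state reproduces the published baseline targets (cardiac
output, systemic and pulmonary pressures, wedge pressure, EDV, ESV)
and then frozen into `builtin_profile()`. The calibration targets
travel with the profile in `target_hemodynamics` but are never read by
the solver.

```{r baseline}
run <- run_steady(experiment_config(builtin_profile("DCM")), duration = 6)
run$summary
```

## The collapsible apex

The suction trigger is taken literally from the hardware it emulates:
the tube engages when LV pressure drops below 0 mmHg. Three modelling
choices deserve explanation.

**Sigmoid target with buckling hysteresis.** A plain sigmoid centred
at the threshold turns the closed loop into a smooth Starling
resistor: the collapse fraction settles just below one half, LV
pressure pins just above zero, flow is throttled, and no discrete
suction event ever occurs. Real collapsed tubes do not behave like
that — buckling is a snap-through instability, and a buckled tube
reopens at a *higher* pressure than the one that closed it. The model
therefore raises the effective threshold by `hysteresis_pressure`
(default 1.2 mmHg) while the tube is engaging. This bistability
produces the per-beat collapse/reopen limit cycle of intermittent
suction and, deeper into hypovolemia, sustained collapse. A side
effect is that the ground-truth label (collapse fraction crossing one
half) can fire with beat-minimum LV pressure marginally above 0 mmHg
(within roughly 1 mmHg), which the tests treat as the engagement band
of the latch.

**Asymmetric time constants.** The squeeze is fast
(`recovery_time_constant`, 40 ms) and the release slow
(`release_time_constant`, 0.5 s). The slow release reproduces the
published DCM suction morphology — an end-systolic transient followed
by a plateau through the rest of the cycle — and keeps the reopening
load on the impeller gentle, which is what keeps the suction-beat
speed pulsatility small compared to non-suction beats. A fast release
produces violent reopening transients with speed excursions far larger
than reported.

**Resistance law.** Inflow resistance interpolates between `r_open`
and `r_collapsed` as `r = r_open + cf^gamma (r_collapsed - r_open)`
with `gamma = collapse_exponent` (default 1, a linear map). Larger
exponents keep the lumen nearly unobstructed until deep collapse;
the default was kept linear because it best reproduces the published
feature separation between suction and non-suction beats.

## Pump telemetry

Hemodynamics are recorded at 1,000 Hz and pump channels at 50 Hz,
matching the recording setup being emulated. Speed, current and power
pass a 15-Hz anti-alias filter. The estimated flow channel is modelled
the way implanted-device firmware reports it: a slow mean-tracking
component (0.2 Hz corner, unit gain — beat and stage means are
faithful) plus a strongly attenuated pulsatile component
(`flow_pulsatility_gain`, default 0.075, behind a 3.5-Hz corner). The
attenuation is what reconciles two published observations that are
mutually inconsistent for a raw flow signal: flow-slope features on
the order of 1 L/min/s at 50 Hz, and visible per-beat waveform
structure. The within-beat shape survives; its amplitude is scaled.

The intra-beat speed signature is calibrated against the published
anchors: at baseline the speed dips at the start of systole and
recovers above the setpoint at end-systole (an excursion on the order
of ±50 rpm); during suction events the torque loss produces a
transient speed rise. Impeller inertia and controller gains were tuned
jointly to those anchors.

## Protocols

`hypovolemia_ramp()` reduces total blood volume stepwise (2% of
baseline per stage, withdrawn proportionally from the venous
reservoirs, with a settling window between stages) until suction is
triggered *and* a beat's 50-Hz flow peak falls below 2 L/min. Two
protocol details are deliberate:

* **Step refinement near onset.** The suction transition is a narrow
  band in volume; a 2% step can leap from "no suction" to continuous
  collapse. While the beat-minimum LV pressure is below 2 mmHg and
  suction is not yet established, the decrement is refined to a
  quarter step so the intermittent-suction band is resolved into
  several stages. A continuous hardware ramp resolves this band
  automatically; a stepped in-silico ramp must do it explicitly.
* **Stop rule on the dynamic flow peak.** The firmware-averaged
  estimated flow suppresses pulsatility, which biases its peak low by
  roughly 1 L/min; the stop criterion is therefore evaluated on the
  true pump flow anti-alias filtered to the 50-Hz grid, restoring the
  intended endpoint severity.

`full_protocol()` runs ramps for both profiles across the speed sweep
(2,500-3,200 rpm), segments every stage with the beat detector,
attaches the simulator's ground-truth flag to every detected beat, and
assembles a labeled dataset with per-profile quotas (about 183/19
suction/non-suction beats for the DCM and 168/21 for the RCM,
matching the published totals). Suction beats are subsampled evenly
over the pooled chronology; non-suction reference beats are subsampled
uniformly per unit of removed volume, as a continuous ramp would
record them. After the stop criterion fires, the terminal volume is
held for additional recorded beats so enough suction beats are
available. In deep DCM suction the flow trace is so flat that not
every recorded beat can be segmented from the estimated flow — the
suction total therefore runs somewhat short of the configured 351 —
and this is a real property of the phenotype (the DCM suction flow
pattern is a low-pulsatility plateau) rather than a tunable artifact.

## Detection pipeline

The beat detector works on the 50-Hz estimated flow only: after light
smoothing and removal of slow baseline drift (running median over
~2.5 s), it keeps one systolic peak per cycle (greedy maxima with a
0.3-s refractory period, merging peak pairs not separated by a
sufficiently deep dip), then places the beat onset at the first local
minimum after the systolic decay — the beginning of diastole —
advanced past any rapid recovery transient such as the reopening
upstroke after a suction spike. Beats are contiguous half-open
windows.

Three features are extracted per beat: the minimum two-point
finite-difference slope of estimated flow (`dqdt_min`, L/min/s), the
minimum impeller speed pulsatility (`d_omega_min`, speed minus the
beat-median speed, rpm; the within-beat reference makes the feature
robust to setpoint drift), and the timing of the maximum positive flow
slope normalized to the beat from the beginning of diastole
(`t_dqdt_max`, wrapped into (0, 1]; a value at the boundary wraps to 1).

The classifier is the fixed-order 3-split tree: a beat is suction if
its flow slope, else its speed pulsatility, else its timing exceeds
the corresponding threshold; ties classify as suction (conservative
for a safety-relevant detector). Because the clinically used
thresholds are not public, `calibrate_thresholds()` grid-searches the
three thresholds maximizing balanced accuracy on a labeled dataset;
the shipped defaults in `tree_thresholds()` are the calibration result
on the shipped full protocol, stored as derived constants.

```{r classify}
tree_thresholds()
```

## Numerical choices

* Fixed-step classic Runge-Kutta at 0.25 ms, four substeps per 1-ms
  hemodynamic sample. The smallest time constants (pump branch during
  collapse, valve-capacitance products) stay several times the step.
* Chamber pressure is floored at -20 mmHg; the floor exists to keep
  the solver out of runaway negative pressures before the collapse
  dynamics engage, and the solver counts how often it is hit.
* The quadratic loss term of the head curve is evaluated as `a2 q|q|`
  so it opposes reverse flow; with the textbook `a2 q^2` a transient
  backflow is accelerated rather than damped.
* The steady-state criterion is a relative change of beat cardiac
  output and EDV below 0.5% over three consecutive beats; runs error
  out after 200 beats without convergence.
* Everything is deterministic by default. Telemetry noise is available
  (zero-mean, seeded, applied to the 50-Hz channels) but off; the
  shipped protocol conditions are noise-free.

## Problem sizes

The default test and acceptance workloads integrate roughly 10-second
baseline records per profile and sixteen hypovolemia ramps of some
15-30 stages at about 20-90 recorded beats each; the full protocol
takes on the order of a minute on one core, and the compiled solver
itself accounts for only a few seconds of that.

## What passing the shipped checks does and does not show

The test bench reproduces, from one coupled model: the baseline
hemodynamic calibration of both phenotypes; the qualitative waveform
signatures (biphasic speed excursion in normal support, apex-pressure
spike and end-systolic flow transient during suction, flat DCM suction
flow versus pulsatile RCM suction flow); the published suction-feature
separation (all six class medians and their orderings); and classifier
performance against simulator ground truth in the published range.

It does not show robustness to real telemetry: clinical waveforms have
wider feature distributions than the simulator produces (sensor noise,
inflow-cannula malposition, arrhythmias, and right-heart or vascular
variation are all absent here), so classifier performance on this
bench is an upper bound, not a clinical estimate. Two quantitative
residuals are known and deliberate: the suction-beat transient speed
rise reaches about +40 rpm rather than the reported ~+100 rpm (all
parameter paths that enlarged it destroyed the published speed
pulsatility medians or the timing structure, which were judged more
central), and the suction beat total runs ~12% short of the configured
count for the reason described under Protocols.
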