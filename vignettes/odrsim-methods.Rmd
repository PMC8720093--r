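---
title: "Modeling a hypoxia-triggered wearable autoinjector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a hypoxia-triggered wearable autoinjector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odrsim)
```

odrsim is a digital twin of a wearable opioid-overdose rescue device. This
vignette is the package's own account of the science: the mechanical model
and its assumptions, the controller semantics, the synthetic physiology,
the numerical choices, and what the simulations do and do not show.

## The mechanism as a dynamical system

The device is a pneumatic autoinjector. A small compressed-gas reservoir
(radius 0.3 cm, height 0.9 cm, so 0.254 cm³) is connected through a control
valve to the lower half of the main fluid cylinder. Opening the valve lets
gas push the fluid piston (radius 1.07 cm) upward; the antidote above it is
incompressible, so the motion is transmitted hydraulically to the smaller
injection piston (radius 0.5 cm), which carries the stowed 30-gauge, 8 mm
hypodermic needle down through a sterile membrane into subcutaneous tissue.
A stop ring halts the injection piston at full stroke; only then does drug
flow through the needle, until 1 ml has left the reservoir and the valve
closes.

The state variables are the two piston positions and velocities, the two
gas inventories, and the cumulative injected volume. Three closures define
the model:

* **Gas.** Isothermal ideal-gas behavior (Boyle's law). We track each
  compartment's inventory as pressure×volume (Pa·m³), which avoids picking
  a gas species, amount or temperature; pressure is inventory divided by
  current volume. The valve is a linear check valve: volumetric flow
  `C_v (P_res − P_low)` referenced to upstream pressure, so the summed
  inventory is conserved exactly. Nothing in the device description fixes a
  valve law; linear conductance is the simplest one-parameter choice, and
  `C_v` is the single calibrated constant in the package (below).
* **Insertion.** While the needle travels, the incompressible fluid couples
  the pistons rigidly: `A_f dx_main = A_n dx_needle`, with the area ratio
  `A_f/A_n ≈ 4.58` acting as a hydraulic lever. The coupled assembly
  carries the 500 g chassis mass as lumped inertia and is retained by the
  11 N/m spring and 11 N·s/m dashpot; tissue resists with a puncture peak
  plus elastic and viscous terms (next section). No fluid leaves through
  the needle in this phase — the flow path is treated as gated until full
  insertion, matching a design in which flow visibly starts only once the
  needle piston has plateaued.
* **Infusion.** With the needle assembly held by the stop ring, the drive
  is quasi-static and viscous-dominated (the Reynolds number in the needle
  at the observed ~1 ml/s is of order 10³ × the radius in mm — laminar):
  Hagen–Poiseuille flow `Q = (P_fluid − P_tissue)/R` with
  `R = 8μL/(πr⁴) ≈ 1.64×10⁹ Pa·s/m³` from the 0.6 mm bore, 8 mm length,
  0.658 cSt kinematic viscosity and 992.562 kg/m³ density. Piston inertia
  is neglected in this phase; fluid pressure equals lower-compartment gas
  pressure. Tissue back-pressure defaults to atmospheric (a config
  override exists), since no subcutaneous pressure is specified anywhere
  in the design.

A useful consequence of these closures: the rate-limiting element is the
valve, not the needle. Driving 1 ml/s through the needle takes only ~1.6 kPa
of head, so the cycle time is set almost entirely by how fast the valve can
move gas inventory — which is why `C_v` is the parameter calibrated to the
cycle-time milestone.

## Free design parameters and their defaults

The published parameter table fixes the geometry, masses and drug
properties but leaves four quantities open. They are set once, as follows,
and shipped in the `"default"` preset:

* **Membrane standoff, 3 mm.** The stow gap between needle tip and skin.
  Forced by arithmetic: an 11 mm injection-piston stroke producing exactly
  8 mm of tissue insertion leaves 3 mm of travel before the skin.
* **Valve conductance, `C_v = 9×10⁻¹⁴ m³/(Pa·s)`.** Calibrated so the
  default first cycle completes in ≈0.9 s, inside the device's 1.2 s
  trigger-to-completion milestone, without being implausibly fast.
* **Tissue force law**: puncture peak 1.6 N across the membrane zone,
  tissue stiffness 220 N/m, damping 2 N·s/m. Chosen once from the range
  reported for fine-gauge needle insertion (peak forces of order 0.5–2 N),
  so the force peak over a default cycle exceeds the 1 N design milestone;
  at full 8 mm depth the elastic term alone is 1.76 N.
* **Gas charge, 20 atm.** The published 5 atm charge stores
  `P₀V_res ≈ 0.13 Pa·m³` of inventory, but holding ~3.9 ml of displaced
  volume (three 1 ml doses plus the insertion sweep) at ambient pressure
  requires ~0.42 Pa·m³ — the design claim that the gas suffices for three
  infusions does not reconcile with the printed reservoir dimensions. We
  therefore keep the printed values as the `"table1"` preset (loading it
  warns, and simulating it stalls mid-insertion with an explicit flag) and
  charge the default preset to 20 atm, the printed geometry's smallest
  round pressure that completes dose 3 briskly (~3 s) with margin.

With these defaults the first cycle runs: insertion complete at 0.41 s,
dose complete at 0.90 s, 1.000 ml delivered, 1.79 N peak force — each
computed, not asserted, and checked in the test suite.

## Controller semantics

The controller is deliberately simple, mirroring the device logic it
emulates. It triggers on the *first* sample with SpO2 ≤ 90 % (single-sample
triggering; a `persistence_samples` knob exists for sensitivity studies but
defaults to 1, faithful to a threshold-only rule). The alert is emitted
exactly once per episode, timestamped with dose 1. Re-checks happen at the
first sample at or after `last_dose_time + 300 s`: still at-or-below
threshold gives the next dose (maximum three), above threshold closes the
episode. Two interpretations were genuinely open:

* *Recovery then re-desaturation.* The device description does not say
  whether a wearer who recovers and later desaturates again starts a new
  episode. We treat the episode as closed after recovery — no further dose
  until an explicit `reset_controller()` — because an autoinjector that
  has partially emptied its reservoir should be inspected before re-arming.
* *After exhaustion.* The controller keeps consuming samples but takes no
  action; the design assumes first responders have arrived by the time a
  fourth dose would be due.

The closed loop (`run_closed_loop()`) drives the mechanical model once per
dose event, with repeat doses continuing from the prior terminal state: the
needle stays inserted, so doses 2 and 3 are infusion-only and take longer
(1.1 s, 3.1 s) as the reservoir pressure falls.

## Synthetic physiology

The trace generator emulates three things: (1) a normal baseline, mean
95 % with 0.5 % Gaussian noise and a 0.5 % diurnal sinusoid, inside the
accepted 93–97 % normal band; (2) an overdose as a *deterministic* ramp
from the noise-free baseline level at onset down to a floor, since the
clinical picture is a sudden, precipitous decline — the preset rate of
4 %/min to a floor of 80 % is illustrative, as no quantitative desaturation
rate for an opioid overdose is established; an exponential-approach shape
is available; (3) optionally, antidote-driven recovery: each dose starts a
one-compartment pharmacokinetic unit (first-order absorption, default
20 h⁻¹; elimination half-life 8 h, nalmefene's plasma half-life), doses
superpose, and concentration drives the signal back toward baseline at a
maximal rate scaled by the saturable term `C/(C + EC50)`. With
`absorption_rate = Inf` the concentration is a pure exponential decay,
halving every 8 h — the analytic anchor the tests check.

The SpO2↔PaO2 mapping is the Severinghaus closed form
`S = 1/(23400/(P³+150P)+1)`; inverting it at 90 % saturation gives
58.7 mmHg, consistent with the ~60 mmHg correspondence used to justify the
trigger threshold (we adopt ±3 mmHg as the tolerance for that "approximate"
anchor). Pulse oximeters read SaO2 with error (reported SD of difference
≈4.7 %); an `oximeter_noise_sd` parameter exists for that, default 0 so
scenario outcomes stay deterministic.

What passing tests therefore show is that the *mechanism and logic* behave
as designed against clean, well-characterized signals. They do not show
robustness to motion artifact, sensor dropout, perfusion-dependent oximeter
bias, or real overdose trajectories — none of which the generator attempts
to emulate.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable), relative tolerance 1e-8,
  absolute 1e-12, with root-finding events for the phase switch, dose
  completion, reservoir exhaustion and stall; trajectories are exported on
  a fixed 1 ms grid.
* The puncture force is a step in the underlying law; integrated naively it
  makes the solver chatter at zero depth (the needle sits exactly at the
  gate). The step's edges are regularized with a 0.2 mm linear ramp —
  continuous in depth, zero at zero travel, and invisible at the reported
  milestones.
* Stall detection: a cycle is declared stalled when reservoir and lower
  compartment have equalized to within 2 kPa short of full stroke (static
  equilibrium against the tissue force — no drive left), when the whole
  inventory is within 100 Pa of back-pressure, or at a `t_max` cap
  (default 120 s). Healthy configurations keep several atmospheres across
  the valve until full stroke, so the equalization root cannot fire
  spuriously.
* The stop ring absorbs the (tiny, ~4 mm/s) piston velocity at the phase
  switch; velocities are zeroed there.
* The dissociation-curve inverse solves the monotone cubic
  `P³ + 150P = 23400·S/(1−S)` by bisection to 1e-13, giving round-trip
  error below 1e-9.
* All external configuration is in the device's engineering units (cm, mm,
  atm, cSt, g) and converted to SI exactly once (`as_si()`); the damper
  constant printed as "11 N/m" is read as 11 N·s/m, since N/m is a
  stiffness unit and the element is a dashpot.
* CSV exports format numbers as `%.12g` so files round-trip to working
  precision; every trace file records its RNG seed in a comment header.

## Problem sizes

The shipped scenarios sample at 1 Hz for 1500 s (one overdose episode with
the full three-dose schedule); trajectories carry ~900–3100 samples per
dose at the 1 ms export grid. These sizes resolve every event of interest
— the fastest feature, the insertion transient, spans hundreds of samples —
while keeping a full closed-loop run to a few seconds of compute.

## Known limitations

The gas model ignores expansion cooling (isothermal assumption); the
tissue model has no needle bending, tissue deformation or depth-dependent
heterogeneity; the valve is linear; alert transport is a logged event, not
a radio; and the recovery pharmacodynamics are a single-effect
phenomenological term, not a mechanistic respiratory model. The published
figure's continuous waveforms are not digitized anywhere in this package;
only the printed milestones (≤1.2 s cycle, 1 ml dose, 8 mm insertion,
>1 N peak force) are reproduced and tested.
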