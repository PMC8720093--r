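# odrsim

Closed-loop, desk-scale simulation of a wearable opioid-overdose rescue
device: a skin-mounted autoinjector that continuously monitors peripheral
oxygen saturation (SpO2) by reflectance pulse oximetry and, when saturation
falls to 90 % or below — the accepted onset of hypoxia, corresponding to an
arterial oxygen partial pressure (PaO2) near 60 mmHg — automatically inserts
a stowed hypodermic needle, injects 1 ml of the opioid antagonist nalmefene
subcutaneously, logs a 911 alert event, and repeats the dose at 5-minute
intervals (three doses maximum) while desaturation persists.

The package is for engineers and modelers studying such hypoxia-triggered
drug-delivery systems: it provides the pneumatic mechanism as a dynamic
model, the dose-controller state machine, a synthetic-physiology layer that
generates the SpO2 signals the controller consumes, and a reproducible
scenario runner.

## The model

**Mechanism.** A compressed-gas reservoir (volume `V_res`, charge `P0`)
feeds the lower fluid compartment through a linear valve,
`Q_valve = C_v (P_res − P_low)`, with gas inventories tracked as
pressure×volume under isothermal (Boyle-law) expansion. The gas pressure
drives the fluid piston (area `A_f`); the incompressible antidote couples it
rigidly to the injection piston (area `A_n`), so `A_f dx_main = A_n dx_needle`
while the needle travels through the sterile-membrane stow gap into tissue
against a puncture + elastic + viscous force law. When the stop ring halts
the injection piston at full stroke (needle fully inserted, 8 mm), infusion
begins: Hagen–Poiseuille flow through the 30-gauge needle,

    Q = (P_fluid − P_atm) / R,   R = 8 μ L / (π r⁴) ≈ 1.64×10⁹ Pa·s/m³,

until the programmed 1 ml dose is out and the valve closes. Integration is
stiff-capable (`deSolve::lsoda`) with root-finding events at the phase
transition, dose completion, reservoir exhaustion and stall.

**Controller.** A four-mode state machine (MONITORING → AWAITING_RECHECK →
RECOVERED/EXHAUSTED) that triggers on the first sample with SpO2 ≤ 90 %,
emits the one-per-episode alert simultaneously with dose 1, and re-checks
the threshold every 300 s for up to three doses.

**Physiology.** Synthetic SpO2 traces: baseline in the normal 93–97 % band
with Gaussian noise and a diurnal sinusoid; overdose as a deterministic
desaturation ramp; optional antidote-driven recovery via a one-compartment
pharmacokinetic model (first-order absorption, 8 h elimination half-life)
with a saturable effect term. The SpO2↔PaO2 mapping uses the Severinghaus
dissociation curve `S = 1/(23400/(P³+150P)+1)`.

## Worked example

```r
library(odrsim)

cfg <- device_preset("default")   # published dimensions, calibrated gas/valve
reservoir_capacity(cfg)
#> [1] 3.95649                     # ml: holds the full 3 x 1 ml schedule
required_length(cfg, include_walls = TRUE)
#> [1] 4                           # cm external length

traj <- simulate_cycle(cfg)       # first injection cycle from trigger
glance(traj)
#> # A tibble: 1 x 6
#>   duration_s injected_ml peak_force_n insertion_depth_mm completed stalled
#>        <dbl>       <dbl>        <dbl>              <dbl> <lgl>     <lgl>
#> 1      0.898           1         1.79                  8 TRUE      FALSE
```

The cycle completes in 0.898 s (within the 1.2 s design milestone),
delivers 1.000 ml, reaches the full 8 mm insertion depth and a 1.79 N peak
needle force. A full overdose scenario:

```r
man <- run_scenario(cfg, "overdose-persistent", seed = 4, out_dir = "out")
man
#> <run_manifest> scenario 'overdose-persistent', seed 4: 3 dose(s), alert at 676 s
#>   dose_1: 0.898 s, 1.0000 ml, peak 1.794 N, depth 8.00 mm
#>   dose_2: 1.114 s, 1.0000 ml, peak 1.760 N, depth 8.00 mm
#>   dose_3: 3.126 s, 1.0000 ml, peak 1.760 N, depth 8.00 mm
```

which writes `trace.csv`, `events.jsonl`, one trajectory CSV per dose and a
`manifest.json` to `out/`. `autoplot(traj)` draws the four-panel cycle
figure (positions, flow, injected volume, force); `autoplot()` on a trace
or closed-loop result plots the SpO2 signal with dose markers. A thin CLI
wrapper with `check-geometry`, `simulate` and `scenario` subcommands ships
in `inst/cli/odrs`.

The `"table1"` preset keeps the published 5 atm gas charge verbatim; it
cannot drive the full schedule (the load warns, and the simulated cycle
stalls mid-insertion with an explicit flag), which is why the default
preset carries a 20 atm charge.

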