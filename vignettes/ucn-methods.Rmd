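---
title: "Modeling the ultra-compact thyristor neuron: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the ultra-compact thyristor neuron: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucnsim)
```

## The model

The ultra-compact neuron (UCN) is a leaky integrate-and-fire (LIF) circuit
whose three functions map onto three components: a capacitor `c1`
*integrates* the input current, a resistor `r_leak` *leaks* the stored
charge, and a silicon controlled rectifier (SCR, a thyristor) *fires*. The
SCR is a hysteretic two-state conductor: blocking, it is a large resistance
`r_off`; when the anode-cathode voltage — here the membrane voltage on
`c1` — reaches the breakover threshold, it switches to a conducting branch
(small resistance `r_on` in series with a forward drop `v_on`) and dumps
the capacitor charge; it switches back only when its current falls to the
holding current `i_hold`. An idealized two-transistor axon stage converts
the discharge current into a clean voltage pulse (`v_pulse` while the
anode current exceeds `i_trigger`).

We deliberately model the SCR phenomenologically rather than at junction
physics level: the neuron dynamics depend on the device only through the
threshold, the holding current, the two resistances and the forward drop.
The gate electrode enters as a single scalar *gate drive* that lowers the
effective breakover threshold linearly
(`v_th0 - alpha_gate * g`, clamped to `[v_th_min, v_th0]`); the resistor
network that would ground the gate in a physical circuit is absorbed into
`alpha_gate`. Reverse bias blocks with `r_off` in both states, as for a
diode.

This makes the simulated object a *hybrid dynamical system*: one to two
continuous states (membrane voltage, plus an input-capacitor voltage or a
feedback variable depending on the variant), one discrete state (the SCR
branch), and two event surfaces — the threshold crossing (the spike) and
the holding-current crossing (the reset).

## Circuit variants

* **base** — current source straight into the membrane node. Sustained
  supra-threshold drive gives tonic spiking; the interspike interval is
  the RC charging time from the reset voltage `v_on + r_on * i_hold` to
  the threshold.
* **phasic** — a series-capacitor (RC differentiator) input network. The
  stimulus amplitude `a` (amperes) maps to a source voltage `a * r_in`
  driving the membrane through `r_in` and `c_in`. Steps pass a transient;
  DC is blocked once `c_in` charges, giving phasic spiking or, with a
  larger `c_in`, a phasic burst.
* **mixed** — the differentiator plus a parallel DC resistor `r_dc`: an
  onset burst from the capacitive path followed by tonic firing from the
  DC path.
* **adaptive** — a spike-triggered feedback variable `w_fb` (jump
  `beta_fb` per spike, exponential decay `r_fb * c_fb`) that acts on the
  SCR gate *and* as a membrane shunt conductance `g_shunt * w_fb`. The
  gate action alone *lowers* the threshold and would shorten the period,
  so the interval lengthening of spike-frequency adaptation is produced
  by the shunt — the standard adaptation-current idiom. Whether a bench
  feedback circuit achieves the lengthening purely through the gate is
  not decidable from circuit topology alone, so both couplings are kept
  and the scenario configuration weights them.
* **inhibitory** — the swapped-polarity topology excited by negative
  current. At this abstraction level the mirrored network obeys exactly
  the base equations with all signs flipped, so it is implemented as a
  sign convention (`polarity = -1`): the internal state integrates `-u`
  and the reported membrane voltage is flipped back. A property test
  asserts the trajectory mirror against the base variant.

### Two mechanism choices worth recording

**Rebound spike.** A mirrored LIF driven by a short negative pulse fires
*during* the pulse (it is simply the first spike of the inhibition-induced
train), not after its release. The rebound behavior — silent during a
hyperpolarizing pulse, one spike just after it ends — is instead produced
here by the differentiator variant: the series capacitor passes a
depolarizing kick at the pulse *offset*. This matches the defining
property of rebound (the spike follows the release of inhibition) and
needs no additional circuitry.

**Class 2 excitability.** A plain LIF has a continuous
frequency-versus-current (f-I) curve: the period diverges logarithmically
at threshold, which is class 1. A capacitive input path only reshapes the
onset transient and leaves the *steady-state* f-I curve continuous, so no
differentiator parameterization can produce a class 2 jump. The shipped
class 2 scenario therefore uses the gate feedback as *facilitation*:
`alpha_gate` large, no shunt, slow feedback decay. Below the zero-drive
threshold nothing fires; just above it the first spike lowers the
effective threshold, and the train continues at the reduced threshold's
finite rate — a genuine discontinuity of the steady-state f-I curve.

## Stimuli

Waveforms (`stimulus()`) are deterministic, piecewise constant or linear,
zero before onset, and right-continuous: steps, pulse trains, paired
pulses (for the integrator behavior), ramps and ramp-then-step (for
accommodation), and negative steps/pulses (inhibition, rebound). The
current-source convention is used throughout; variants with a voltage
input network convert through `r_in` as above.

## Numerical integration

Between events the system is advanced by `deSolve::lsodar` — an adaptive,
stiff-capable stepper with root finding. Stiffness is real: in the
conducting branch the membrane time constant collapses from
`r_leak * c1` (10 ms in the canonical circuit) to `r_on * c1` (10 us).
Each mode exposes exactly one root function (its exit event); `lsodar`
stops at the root, the discrete transition (including the per-spike
`w_fb` jump) is applied exactly once, and integration restarts.
Integration segments are split at stimulus breakpoints so the stepper
never crosses a discontinuity of `u(t)`.

Numerical choices, all overridable per call: relative tolerance `1e-8`,
absolute `1e-10` (states are volt-scale), maximum step `dt_max = 1e-4` s
(a quarter of the smallest blocking-phase time constant in the shipped
scenarios), trace sampling `t_end / 5000` by default with event times
always included and duplicated (pre/post switch), and a minimum dwell
time of `1e-7` s per mode — repeated violation aborts with a diagnostic
rather than silently coarsening, which would mask genuine chattering.
Traces are written as CSV with `%.17g` formatting, which round-trips IEEE
doubles exactly. The engine contains no randomness: repeated runs are
bit-identical, which the test suite asserts at file-byte level for the
whole battery.

A deliberately naive reference engine (`simulate_euler`, explicit Euler
at a fixed step with events placed inside a step by bisection on the
linear interpolant, via `locate_event`) cross-checks the event-driven
integrator on the tonic scenario. The comparison convention: spike counts
must agree exactly, per-spike times within 10 us, and the membrane
trajectories within 1% of the threshold voltage over the blocking
(integrate) phase. Samples inside the ~70 us discharge are excluded from
the voltage comparison: a first-order method's O(dt) spike-time bias
(about 0.3 us per cycle at `dt = 1e-7` s) accumulates over a 160 ms run
and is amplified by the ~4e4 V/s discharge slope into apparent
volt-scale differences that reflect event placement, not trajectory
error.

For closed-form validation, an *instantaneous-discharge idealization* is
used: `v_on = 0`, `r_on = 1` ohm, `r_off = 1e12` ohm. Its steady period
matches the textbook LIF formula
`T = -tau * ln(1 - v_th / (A * r_leak))`; the large `r_off` matters
because the formula neglects the blocking-state device leak, which near
threshold competes with the vanishing net charging current.

## Spike analysis and classification

`detect_spikes` finds upward crossings of the output voltage through
`v_pulse / 2` (merge window 0.2 ms); ISIs, the adaptation index
`(ISI_last - ISI_first) / (ISI_last + ISI_first)`, burst grouping
(internal gaps at most `isi_intra = 3` ms, separation at least
`isi_inter = 15` ms), first-spike latency, and steady-state f-I curves
(frequency measured over the second half of the window) feed a
fixed-order predicate ladder (`classify_behavior`), total and
deterministic. The behaviors are defined in the source literature only by
figure; the predicates make them testable, and their thresholds are
explicit, configurable numbers:

* tonic: at least 5 spikes, no bursts, |AI| < 0.1, spanning > 80% of the
  stimulus;
* phasic spiking: exactly one spike within 5 tau of onset;
* phasic bursting: exactly one onset burst, nothing after;
* mixed: an onset burst then at least 3 non-burst spikes;
* adaptation: at least 5 spikes, strictly lengthening ISIs, AI >= 0.15;
* spike latency: first spike later than 3x the tonic-reference latency
  `tau * ln 3` (the closed-form first-spike latency at 1.5x the rheobase
  drive);
* integrator / accommodation: two-run predicates (fires for the
  close-paired pulses and not the wide pair; silent for the slow ramp and
  firing for the equal-amplitude step);
* class 1 / class 2: from the f-I curve — smallest nonzero frequency
  below `f_eps = 25` Hz, versus a jump from zero to at least
  `f_jump = 100` Hz. With the canonical tau of 10 ms these play the role
  that a few hertz plays at biological time constants; the hardware runs
  a scale faster than biology, and no biological calibration is
  attempted.

The split between "phasic bursting" and "mixed" has no quantitative
criterion in the source literature; the burst-grouping convention above
is this package's. The mixed scenario relaxes the grouping thresholds
slightly (`isi_intra` 4 ms, `isi_inter` 12 ms, declared in its config):
the transition from the capacitive burst to DC tonic firing passes
through one intermediate interval, which is physics, not noise.

## The shipped scenario battery

Twelve scenario fixtures (JSON, `inst/extdata/scenarios/`) pair a circuit
variant with a stimulus and an expected label, one per canonical
behavior: tonic, phasic spiking, phasic bursting, mixed, spike-frequency
adaptation, class 1, class 2, spike latency, integrator, accommodation,
rebound, and inhibition-induced spiking. Component lists for the original
bench circuits are not publicly available, so the fixtures declare their
own values, chosen once from explicit constraints:

* `r_leak = 1e6` ohm, `c1 = 10` nF: tau = 10 ms, millisecond-scale
  traces;
* sustained drive currents below `i_hold` (here 2x threshold = 4 uA
  against `i_hold = 10` uA): during the discharge the input current flows
  through the conducting SCR, and the device can only release if that
  current is below the holding current — a real latch-up constraint of
  thyristor circuits;
* scenario `r_on = 1000` ohm so the conducting-phase time constant
  (10 us) is well resolved both by the adaptive stepper and by the
  `1e-7` s fixed-step reference;
* axon `i_trigger = 0.2` mA, below the weakest discharge peak
  (`(v_th_min - v_on) / r_on`) among the scenarios;
* the burst scenarios raise `i_hold` to 30 uA to admit the stronger
  transient input current their differentiator passes.

The battery (about 30 simulations, durations 0.05–0.3 s, roughly 15 s of
wall time on one CPU) is the package's headline check: each scenario must
classify to its intended label, giving twelve distinct behaviors.

## What passing does and does not show

The battery demonstrates that the *idealized* UCN — linear two-branch
SCR, comparator axon, exact component values, no noise — reproduces the
twelve qualitative firing patterns, and that the engine agrees with
closed-form LIF results and an independent reference integrator. It does
not validate junction-level transients (the known transient mismatch near
the threshold input in hardware/SPICE comparisons is out of scope),
component tolerances or mismatch, temperature effects, dV/dt-induced
false triggering, or multi-neuron coupling. The "delayed burst" pattern
observed on bench hardware has no disclosed circuit and is excluded; it
would make a natural thirteenth scenario if a plausible parameterization
is found.
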