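# ucnsim

Hybrid simulation of the **ultra-compact neuron (UCN)**: a leaky
integrate-and-fire circuit whose firing element is a silicon controlled
rectifier (SCR, a thyristor). The package is for computational
neuroscientists and neuromorphic-circuit engineers who want to explore,
test and classify the spiking repertoire of thyristor-based neuron
circuits without a SPICE netlist.

## The model

The soma is three components: a membrane capacitor $C_1$ integrates the
input current, a leak resistor $R_{leak}$ drains it, and the SCR fires.
The SCR is a hysteretic two-state conductor with a gate-modulated
breakover threshold:

* blocking: $i = v_{ak} / R_{off}$, switching to conducting when
  $v_{ak} \ge V_{th}(g) = \mathrm{clamp}(V_{th0} - \alpha_g\, g,\;
  V_{th,min}, V_{th0})$;
* conducting: $i = \max(0, v_{ak} - V_{on}) / R_{on}$, switching back
  when $i \le I_{hold}$.

Between switches the membrane obeys charge balance,

$$C_1 \frac{dV_{mem}}{dt} = u(t) - \frac{V_{mem}}{R_{leak}}
  - i_{SCR}(V_{mem}) \;(+\; \text{variant terms}),$$

and an idealized axon stage emits $V_{pulse}$ while the SCR current
exceeds a trigger level. Circuit variants add an RC-differentiator input
(phasic/mixed behaviors), a spike-triggered gate-feedback variable with a
membrane shunt (adaptation, class 2 excitability), or a mirrored
topology for negative-polarity input (inhibition-induced behaviors). The
result is a hybrid dynamical system — continuous states plus one
discrete device state — integrated with `deSolve::lsodar`, whose root
finder localizes every switching event. The engine is fully
deterministic.

See the methods vignette (`vignettes/ucn-methods.Rmd`) for the model
assumptions, the classifier predicate table and all numerical choices.

## Worked example

Tonic spiking of the base block under a sustained 4 uA step (twice the
threshold drive):

```r
library(ucnsim)
sys <- ucn_circuit("base", circuit_params(c1 = 1e-8, r_leak = 1e6),
                   scr_params(r_on = 1000), axon_params(i_trigger = 2e-4))
sys
#> UCN circuit, variant 'base'
#>   continuous states : v_mem
#>   membrane tau      : 0.01 s (c1 1e-08 F, r_leak 1e+06 ohm)
#>   SCR threshold     : 2 V, holding current 1e-05 A

st <- stimulus("step", t_on = 0.01, amplitude = 4e-6)
tr <- simulate(sys, stimulus = st, t_end = 0.16)
train <- detect_spikes(tr)
train
#> Spike train: 29 spikes, t in [0.0172592, 0.157818] s

isis <- interspike_intervals(train)
c(mean_isi = mean(isis), ai = adaptation_index(isis))
#> mean ISI 0.00502 s, adaptation index ~ 0 (regular firing)

classify_behavior(tr, st)
#> [1] "tonic_spiking"

plot(tr)   # stacked I_in / V_mem / V_out panels
```

The 5.02 ms interspike interval is the RC charging time from the reset
voltage (0.81 V) back to the 2 V threshold under the 4 uA drive, plus the
~70 us discharge; the near-zero adaptation index confirms regular
firing.

The twelve shipped scenarios (one per canonical behavior, JSON under
`inst/extdata/scenarios/`) run end to end with:

```r
run_battery(out_dir = "ucn-out")
#> UCN behavior battery: 12 / 12 scenarios reproduced (12 distinct behaviors)
```

or from a shell: `Rscript inst/cli/ucn.R battery --out ucn-out`
(also `list` and `run --config <file>`).

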