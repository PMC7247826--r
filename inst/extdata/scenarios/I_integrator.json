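{
  "scenario_id": "I_integrator",
  "expected_label": "integrator",
  "variant": "base",
  "circuit": {"c1": 1e-8, "r_leak": 1e6},
  "scr": {"r_on": 1000},
  "axon": {"i_trigger": 2e-4},
  "stimuli": [
    {"kind": "paired_pulse", "t_on": 0.005, "amplitude": 7e-6,
     "width": 2e-3, "gap": 1e-3},
    {"kind": "paired_pulse", "t_on": 0.005, "amplitude": 7e-6,
     "width": 2e-3, "gap": 2e-2}
  ],
  "duration_s": 0.05,
  "dt_max_s": 1e-4
}
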