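{
  "scenario_id": "K_rebound",
  "expected_label": "rebound_spike",
  "variant": "phasic",
  "circuit": {"c1": 1e-8, "r_leak": 1e6, "c_in": 1e-8, "r_in": 1e4},
  "scr": {"r_on": 1000},
  "axon": {"i_trigger": 2e-4},
  "stimulus": {"kind": "negative_pulse", "t_on": 0.02, "amplitude": 6e-4,
               "width": 0.03},
  "duration_s": 0.12,
  "dt_max_s": 1e-4
}
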