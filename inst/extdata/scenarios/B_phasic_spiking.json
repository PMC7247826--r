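{
  "scenario_id": "B_phasic_spiking",
  "expected_label": "phasic_spiking",
  "variant": "phasic",
  "circuit": {"c1": 1e-8, "r_leak": 1e6, "c_in": 1e-8, "r_in": 1e4},
  "scr": {"r_on": 1000},
  "axon": {"i_trigger": 2e-4},
  "stimulus": {"kind": "step", "t_on": 0.01, "amplitude": 6e-4},
  "duration_s": 0.08,
  "dt_max_s": 1e-4
}
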