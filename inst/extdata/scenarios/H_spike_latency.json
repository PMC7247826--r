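{
  "scenario_id": "H_spike_latency",
  "expected_label": "spike_latency",
  "variant": "base",
  "circuit": {"c1": 1e-8, "r_leak": 1e6},
  "scr": {"r_on": 1000},
  "axon": {"i_trigger": 2e-4},
  "stimulus": {"kind": "step", "t_on": 0.005, "amplitude": 2.2044e-6},
  "duration_s": 0.08,
  "dt_max_s": 1e-4
}
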