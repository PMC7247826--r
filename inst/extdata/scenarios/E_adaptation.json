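{
  "scenario_id": "E_adaptation",
  "expected_label": "spike_frequency_adaptation",
  "variant": "adaptive",
  "circuit": {"c1": 1e-8, "r_leak": 1e6, "beta_fb": 1, "g_shunt": 1e-7,
              "r_fb": 6e6, "c_fb": 1e-8},
  "scr": {"r_on": 1000, "alpha_gate": 0.01, "v_th_min": 1.2},
  "axon": {"i_trigger": 2e-4},
  "stimulus": {"kind": "step", "t_on": 0.005, "amplitude": 4e-6},
  "duration_s": 0.11,
  "dt_max_s": 1e-4
}
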