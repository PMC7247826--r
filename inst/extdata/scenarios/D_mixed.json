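{
  "scenario_id": "D_mixed",
  "expected_label": "mixed",
  "variant": "mixed",
  "circuit": {"c1": 1e-8, "r_leak": 1e6, "c_in": 3e-8, "r_in": 2e5,
              "r_dc": 1.6e6},
  "scr": {"r_on": 1000, "i_hold": 3e-5},
  "axon": {"i_trigger": 2e-4},
  "stimulus": {"kind": "step", "t_on": 0.01, "amplitude": 3e-5},
  "duration_s": 0.2,
  "dt_max_s": 1e-4,
  "rules": {"isi_intra": 4e-3, "isi_inter": 1.2e-2}
}
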