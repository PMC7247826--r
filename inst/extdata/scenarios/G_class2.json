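{
  "scenario_id": "G_class2",
  "expected_label": "class2_excitable",
  "variant": "adaptive",
  "circuit": {"c1": 1e-8, "r_leak": 1e6, "beta_fb": 1, "g_shunt": 0,
              "r_fb": 1e7, "c_fb": 1e-6},
  "scr": {"r_on": 1000, "alpha_gate": 1, "v_th_min": 1.2},
  "axon": {"i_trigger": 2e-4},
  "sweep": {"amplitudes": [1.98e-6, 2.09e-6, 2.178e-6, 2.2022e-6,
                           2.222e-6, 2.266e-6, 2.332e-6, 2.42e-6,
                           2.64e-6, 2.86e-6],
            "duration_s": 0.3},
  "duration_s": 0.3,
  "dt_max_s": 1e-4
}
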