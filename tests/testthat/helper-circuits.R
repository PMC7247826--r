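# shared fixture builders: every object is constructed in code

# scenario-scale SCR/axon used by the shipped battery (tau_on = 10 us)
test_scr <- function(...) scr_params(r_on = 1000, ...)
test_axon <- function() axon_params(i_trigger = 2e-4)

# the canonical membrane: tau = r_leak * c1 = 10 ms
test_base <- function(scr = test_scr()) {
  ucn_circuit("base", circuit_params(), scr, test_axon())
}

# idealized LIF block matching the closed-form period formula: negligible
# forward drop, near-instant discharge, negligible blocking leak
ideal_lif <- function() {
  ucn_circuit("base", circuit_params(),
              scr_params(v_on = 0, r_on = 1, r_off = 1e12, i_hold = 1e-5),
              test_axon())
}

# closed-form steady LIF frequency for a sustained drive a (A), reset at 0
lif_freq <- function(a, r_leak = 1e6, tau = 1e-2, v_th = 2) {
  ifelse(a * r_leak <= v_th, 0, 1 / (-tau * log(1 - v_th / (a * r_leak))))
}

# a synthetic trace with rectangular output pulses at given onsets
pulse_trace <- function(onsets, width = 5e-4, v_pulse = 5, t_end = NULL,
                        dt = 1e-5) {
  if (is.null(t_end)) t_end <- max(onsets) + 10 * width
  t <- seq(0, t_end, by = dt)
  v <- numeric(length(t))
  for (o in onsets) v[t >= o & t < o + width] <- v_pulse
  structure(data.frame(t = t, u = 0, v_mem = 0, v_out = v,
                       conducting = as.integer(v > 0)),
            class = c("ucn_trace", "data.frame"))
}

shipped_scenarios <- function() {
  system.file("extdata", "scenarios", package = "ucnsim")
}
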