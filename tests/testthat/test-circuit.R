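test_that("variants compile with exactly their active states", {
  expect_equal(ucn_circuit("base")$states, "v_mem")
  ph <- ucn_circuit("phasic", circuit_params(c_in = 1e-8))
  expect_equal(ph$states, c("v_mem", "v_cin"))
  ad <- ucn_circuit("adaptive", circuit_params(beta_fb = 1))
  expect_equal(ad$states, c("v_mem", "w_fb"))
  inh <- ucn_circuit("inhibitory")
  expect_equal(inh$states, "v_mem")
  expect_equal(inh$circuit$polarity, -1)
  expect_equal(ucn_circuit("base")$n_events, 2L)
})

test_that("variant/parameter mismatches are configuration errors naming the element", {
  expect_error(ucn_circuit("phasic", circuit_params(c_in = 0)), "c_in")
  expect_error(ucn_circuit("mixed", circuit_params(c_in = 1e-8)), "r_dc")
  expect_error(ucn_circuit("adaptive", circuit_params(beta_fb = 0)),
               "beta_fb")
  expect_error(ucn_circuit("base", circuit_params(polarity = -1)),
               "polarity")
})

test_that("membrane derivative matches the RC closed forms while blocking", {
  sys <- ideal_lif()
  tau <- ucn_tau(sys)
  # free decay: dv/dt = -v / tau at u = 0 (blocking leak negligible)
  d <- membrane_derivative(sys, 0, 1, u = 0, conducting = FALSE)
  expect_equal(d$dy[1], -1 / tau * 1, tolerance = 1e-5)
  # subthreshold fixed point v = u * r_leak has zero rate
  d2 <- membrane_derivative(sys, 0, 1.5, u = 1.5e-6, conducting = FALSE)
  expect_equal(d2$dy[1], 0, tolerance = 1e-3 / tau)
  # feedback variable decays with its own RC constant
  ad <- ucn_circuit("adaptive",
                    circuit_params(beta_fb = 1, r_fb = 6e6, c_fb = 1e-8))
  d3 <- membrane_derivative(ad, 0, c(0, 0.5), u = 0, conducting = FALSE)
  expect_equal(d3$dy[2], -0.5 / (6e6 * 1e-8))
})

test_that("simulated blocking dynamics match the analytic RC solution", {
  # sub-threshold initial value relaxing through the leak: v = V0 exp(-t/tau)
  sys <- ideal_lif()
  tau <- ucn_tau(sys)
  st <- stimulus("step", t_on = 1, amplitude = 0)  # never turns on
  tr <- simulate(sys, stimulus = st, t_end = 2 * tau, y0 = 1)
  v_ref <- exp(-tr$t / tau)
  expect_lt(max(abs(tr$v_mem - v_ref)) / max(v_ref), 1e-3)
  expect_equal(nrow(attr(tr, "events")), 0L)
})

test_that("charge is conserved at the membrane node for every variant", {
  cases <- list(
    list(sys = ucn_circuit("base"), y = 1.2),
    list(sys = ucn_circuit("phasic", circuit_params(c_in = 3e-8)),
         y = c(0.7, 2.1)),
    list(sys = ucn_circuit("mixed", circuit_params(c_in = 3e-8, r_dc = 2e6)),
         y = c(1.1, -0.4)),
    list(sys = ucn_circuit("adaptive",
                           circuit_params(beta_fb = 1, g_shunt = 1e-7)),
         y = c(1.5, 3)),
    list(sys = ucn_circuit("inhibitory"), y = 0.9))
  for (cs in cases) {
    for (cond in c(FALSE, TRUE)) {
      d <- membrane_derivative(cs$sys, 0, cs$y, u = 3e-6, conducting = cond)
      branch_sum <- sum(unlist(d$currents[setdiff(names(d$currents),
                                                  "i_cin_branch")]))
      imax <- max(abs(unlist(d$currents)), 1e-12)
      expect_lt(abs(cs$sys$circuit$c1 * d$dy[1] - branch_sum) / imax, 1e-9)
    }
  }
})

test_that("the inhibitory variant mirrors the base trajectory", {
  scr <- test_scr()
  base <- ucn_circuit("base", circuit_params(), scr, test_axon())
  inh <- ucn_circuit("inhibitory", circuit_params(polarity = -1), scr,
                     test_axon())
  st_pos <- stimulus("step", t_on = 0.01, amplitude = 4e-6)
  st_neg <- stimulus("negative_step", t_on = 0.01, amplitude = 4e-6)
  tr_b <- simulate(base, stimulus = st_pos, t_end = 0.06)
  tr_i <- simulate(inh, stimulus = st_neg, t_end = 0.06)
  expect_equal(tr_i$t, tr_b$t)
  expect_equal(tr_i$v_mem, -tr_b$v_mem)
  expect_equal(tr_i$v_out, tr_b$v_out)   # output pulses stay positive
  expect_equal(attr(tr_i, "events"), attr(tr_b, "events"))
})
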