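test_that("free decay reaches exp(-1) after one time constant", {
  cc <- circuit_params(c1 = 1e-8, r_leak = 1e5)   # tau = 1 ms
  sys <- ucn_circuit("base", cc, scr_params(r_off = 1e12), test_axon())
  st <- stimulus("step", t_on = 1, amplitude = 0)
  tr <- simulate(sys, stimulus = st, t_end = 1.1e-3, y0 = 1)
  v_1ms <- tr$v_mem[which.min(abs(tr$t - 1e-3))]
  expect_equal(v_1ms, exp(-1), tolerance = 1e-3)
})

test_that("sub-threshold drive produces no switching over 100 tau", {
  cc <- circuit_params(c1 = 1e-8, r_leak = 1e5)   # tau = 1 ms
  sys <- ucn_circuit("base", cc, scr_params(r_off = 1e12), test_axon())
  st <- stimulus("step", t_on = 0, amplitude = 0.99 * 2 / 1e5)
  tr <- simulate(sys, stimulus = st, t_end = 0.1)
  expect_equal(nrow(attr(tr, "events")), 0L)
  expect_lt(max(tr$v_mem), 2)
})

test_that("steady ISI at twice-threshold drive equals tau*ln(2)", {
  sys <- ideal_lif()
  tau <- ucn_tau(sys)
  st <- stimulus("step", t_on = 0, amplitude = 2 * 2 / 1e6)
  tr <- simulate(sys, stimulus = st, t_end = 0.08)
  isis <- diff(event_times(tr))
  expect_gt(length(isis), 5)
  expect_lt(max(abs(isis - tau * log(2))) / (tau * log(2)), 0.02)
})

test_that("locate_event refines a bracketed sign change by bisection", {
  expect_equal(locate_event(function(t) t - 0.5, 0, 1, 1e-9), 0.5,
               tolerance = 1e-8)
  # first root inside the bracket is returned
  g <- function(t) (t - 0.25) * (t - 0.75)
  expect_equal(locate_event(g, 0, 0.5, 1e-9), 0.25, tolerance = 1e-8)
  expect_error(locate_event(function(t) 1 + t, 0, 1), "sign change")
})

test_that("switching events alternate and conducting episodes have duration", {
  sys <- test_base()
  st <- stimulus("step", t_on = 0.01, amplitude = 4e-6)
  tr <- simulate(sys, stimulus = st, t_end = 0.08)
  ev <- attr(tr, "events")
  expect_gt(nrow(ev), 4)
  expect_true(all(diff(ev$time) > 0))
  dirs <- ev$direction
  expect_true(all(dirs[seq(1, length(dirs), by = 2)] == "up"))
  expect_true(all(dirs[seq(2, length(dirs), by = 2)] == "down"))
  on_time <- ev$time[dirs == "down"] - ev$time[dirs == "up"][
    seq_len(sum(dirs == "down"))]
  expect_true(all(on_time > 0))
})

test_that("spike times are stable under step-size refinement", {
  sys <- test_base()
  st <- stimulus("step", t_on = 0.005, amplitude = 4e-6)
  t1 <- event_times(simulate(sys, stimulus = st, t_end = 0.04,
                             dt_max = 1e-4))
  t2 <- event_times(simulate(sys, stimulus = st, t_end = 0.04,
                             dt_max = 5e-5))
  expect_equal(length(t1), length(t2))
  expect_lt(max(abs(t1 - t2)), 1e-8)
})

test_that("identical configurations give bit-identical traces", {
  sys <- test_base()
  st <- stimulus("step", t_on = 0.01, amplitude = 4e-6)
  tr1 <- simulate(sys, stimulus = st, t_end = 0.05)
  tr2 <- simulate(sys, stimulus = st, t_end = 0.05)
  expect_identical(tr1$t, tr2$t)
  expect_identical(tr1$v_mem, tr2$v_mem)
  expect_identical(tr1$v_out, tr2$v_out)
})

test_that("trace columns are aligned, ordered, duplicated only at events", {
  sys <- test_base()
  st <- stimulus("step", t_on = 0.01, amplitude = 4e-6)
  tr <- simulate(sys, stimulus = st, t_end = 0.05)
  expect_true(all(diff(tr$t) >= 0))
  dup_t <- tr$t[which(diff(tr$t) == 0)]
  ev <- attr(tr, "events")
  expect_true(all(dup_t %in% ev$time))
  # pre/post rows at an up event disagree on the discrete state
  k <- which(tr$t == ev$time[ev$direction == "up"][1])
  expect_equal(tr$conducting[k], c(0L, 1L))
})

test_that("trace CSV round-trips exactly at the documented precision", {
  sys <- test_base()
  st <- stimulus("step", t_on = 0.01, amplitude = 4e-6)
  tr <- simulate(sys, stimulus = st, t_end = 0.03)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_identical(back$t, tr$t)
  expect_identical(back$v_mem, tr$v_mem)
  expect_identical(back$conducting, tr$conducting)
})

test_that("malformed trace files are rejected with a named column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,u,v_mem", "0,0,0"), f)
  expect_error(read_trace(f), "v_out")
  f2 <- withr::local_tempfile(fileext = ".csv")
  file.create(f2)
  expect_error(read_trace(f2), "empty")
})

test_that("simulate validates its preconditions", {
  sys <- test_base()
  st <- stimulus("step", t_on = 0, amplitude = 1e-6)
  expect_error(simulate(sys, stimulus = st, t_end = -1), "t_end")
  expect_error(simulate(sys, stimulus = st, t_end = 1, dt_max = 1e-4,
                        event_tol = 1e-3), "event_tol")
})
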