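test_that("detect_spikes finds rectangular pulse onsets and merges close ones", {
  tr <- pulse_trace(c(0.01, 0.015, 0.02))
  expect_equal(detect_spikes(tr, v_half = 2.5)$times, c(0.01, 0.015, 0.02))
  # all-quiet trace: empty train
  tr0 <- pulse_trace(0.01)
  tr0$v_out[] <- 0
  expect_length(detect_spikes(tr0, v_half = 2.5)$times, 0)
  # two crossings 0.1 ms apart merge under a 1 ms refractory window
  trm <- pulse_trace(c(0.01, 0.0101), width = 4e-5, dt = 1e-5)
  expect_length(detect_spikes(trm, v_half = 2.5, t_refractory = 1e-3)$times,
                1)
  expect_error(detect_spikes(pulse_trace(0.01)[0, ]), "empty")
})

test_that("detection distributes over concatenation across a long gap", {
  a <- pulse_trace(c(0.01, 0.02), t_end = 0.05)
  b <- pulse_trace(c(0.01, 0.03), t_end = 0.05)
  b$t <- b$t + 0.05
  joined <- structure(rbind(as.data.frame(a), as.data.frame(b)),
                      class = c("ucn_trace", "data.frame"))
  got <- detect_spikes(joined, v_half = 2.5, t_refractory = 1e-3)$times
  want <- c(detect_spikes(a, v_half = 2.5, t_refractory = 1e-3)$times,
            detect_spikes(b, v_half = 2.5, t_refractory = 1e-3)$times)
  expect_equal(got, want)
})

test_that("interspike intervals and adaptation index follow their definitions", {
  expect_equal(interspike_intervals(c(0, 1, 3)), c(1, 2))
  expect_equal(interspike_intervals(c(0, 1)), 1)
  expect_error(interspike_intervals(5), "at least 2")
  expect_equal(adaptation_index(c(1, 1, 1)), 0)
  expect_equal(adaptation_index(c(1, 2, 3)), 0.5)
  expect_equal(adaptation_index(c(3, 2, 1)), -0.5)
  expect_error(adaptation_index(1), "at least 2")
})

test_that("adaptation index is antisymmetric under ISI reversal", {
  set.seed(7)
  for (k in 1:20) {
    isis <- runif(sample(2:10, 1), 1e-3, 2e-2)
    ai <- adaptation_index(isis)
    expect_equal(adaptation_index(rev(isis)), -ai)
    expect_true(ai > -1 && ai < 1)
  }
})

test_that("burst grouping respects intra/inter thresholds", {
  sp <- c(0, 1, 2, 50, 51, 52) * 1e-3
  b <- detect_bursts(sp, isi_intra = 5e-3, isi_inter = 2e-2)
  expect_length(b, 2)
  expect_equal(lengths(b), c(3L, 3L))
  # evenly spaced spikes at 10 ms: all singleton groups, no bursts
  expect_length(detect_bursts(seq(0, 0.1, by = 1e-2), isi_intra = 5e-3,
                              isi_inter = 2e-2), 0)
  expect_length(detect_bursts(numeric(0)), 0)
  # a tight group shadowed by a nearby spike is not a separated burst
  expect_length(detect_bursts(c(0, 1e-3, 2e-3, 8e-3), isi_intra = 3e-3,
                              isi_inter = 1.5e-2), 0)
  expect_error(detect_bursts(sp, isi_intra = 2e-2, isi_inter = 1e-2),
               "isi_intra")
})

test_that("latency measures first spike after onset", {
  expect_equal(latency(c(12e-3), t_on = 10e-3), 2e-3)
  expect_equal(latency(c(10e-3), t_on = 10e-3), 0)
  expect_error(latency(c(5e-3), t_on = 10e-3), "no spike")
})

test_that("excitability classification applies the continuity/jump rules", {
  fi <- function(f) data.frame(amplitude = seq_along(f), frequency = f)
  expect_equal(classify_excitability(fi(c(0, 0, 0.5, 1.2, 2.0)), f_eps = 1,
                                     f_jump = 20), "class1_excitable")
  expect_equal(classify_excitability(fi(c(0, 0, 40, 45)), f_eps = 1,
                                     f_jump = 20), "class2_excitable")
  expect_equal(classify_excitability(fi(c(0, 0, 0))), "unclassified")
  expect_equal(classify_excitability(fi(c(5, 10))), "unclassified")
})

test_that("f_i_curve returns zero below threshold and validates input", {
  sys <- test_base()
  fi <- f_i_curve(sys, c(5e-7, 1e-6, 1.5e-6), duration = 0.05)
  expect_equal(fi$frequency, c(0, 0, 0))
  expect_error(f_i_curve(sys, c(2e-6, 1e-6), duration = 0.05), "sorted")
})

test_that("the classifier is total and deterministic on edge traces", {
  st <- stimulus("step", t_on = 0.01, amplitude = 1e-6)
  quiet <- pulse_trace(0.02)
  quiet$v_out[] <- 0
  rules <- behavior_rules(tau = 1e-2)
  expect_equal(classify_behavior(quiet, st, rules), "silent")
  # an oddball spike pattern still yields a label
  odd <- pulse_trace(c(0.012, 0.013, 0.05), t_end = 0.2)
  l1 <- classify_behavior(odd, st, rules)
  expect_true(l1 %in% behavior_labels())
  expect_identical(l1, classify_behavior(odd, st, rules))
})

test_that("single-run predicates label constructed spike patterns", {
  st <- stimulus("step", t_on = 0.01, amplitude = 1e-6)
  rules <- behavior_rules(tau = 1e-2)
  # regular sustained firing spanning the stimulus
  tonic <- pulse_trace(seq(0.015, 0.29, by = 0.02), t_end = 0.3)
  expect_equal(classify_behavior(tonic, st, rules), "tonic_spiking")
  # one onset spike
  one <- pulse_trace(0.02, t_end = 0.2)
  expect_equal(classify_behavior(one, st, rules), "phasic_spiking")
  # one onset burst, nothing after
  burst <- pulse_trace(c(0.012, 0.013, 0.014), t_end = 0.2)
  expect_equal(classify_behavior(burst, st, rules), "phasic_bursting")
  # burst then sustained singles
  mx <- pulse_trace(c(0.012, 0.013, 0.014, 0.05, 0.08, 0.11, 0.14),
                    t_end = 0.2)
  expect_equal(classify_behavior(mx, st, rules), "mixed")
  # strictly lengthening ISIs
  ad <- pulse_trace(0.01 + cumsum(c(0.004, 0.005, 0.0062, 0.0078, 0.01)),
                    t_end = 0.08)
  expect_equal(classify_behavior(ad, st, rules),
               "spike_frequency_adaptation")
  # one very delayed spike
  late <- pulse_trace(0.075, t_end = 0.2)
  expect_equal(classify_behavior(late, st, rules), "spike_latency")
})
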