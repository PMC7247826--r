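#' Detect spikes in a trace's output voltage
#'
#' A spike onset is an upward crossing of `v_out` through `v_half`;
#' crossings closer than `t_refractory` to the previous accepted onset
#' are merged.
#'
#' @param trace a `ucn_trace` (or data frame with `t` and `v_out`).
#' @param v_half detection level (V); defaults to half the axon pulse
#'   height when the trace carries its system, else half the observed
#'   maximum.
#' @param t_refractory merge window (s).
#' @return An object of class `"spike_train"`: list with `times` (s) and
#'   `source`.
#' @export
detect_spikes <- function(trace, v_half = NULL, t_refractory = 2e-4) {
  if (is.null(trace) || nrow(trace) == 0) stop("detect_spikes: empty trace")
  if (t_refractory < 0) stop("detect_spikes: need t_refractory >= 0")
  if (is.null(v_half)) {
    sys <- attr(trace, "system")
    v_half <- if (!is.null(sys)) sys$axon$v_pulse / 2 else max(trace$v_out) / 2
  }
  v <- trace$v_out
  up <- which(v[-1L] >= v_half & v[-length(v)] < v_half) + 1L
  times <- trace$t[up]
  if (length(times) > 1L) {
    kept <- times[1L]
    for (tt in times[-1L])
      if (tt - kept[length(kept)] >= t_refractory) kept <- c(kept, tt)
    times <- kept
  }
  structure(list(times = times, source = attr(trace, "source")),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes", length(x$times)))
  if (length(x$times))
    cat(sprintf(", t in [%g, %g] s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' Interspike intervals
#'
#' @param train a [detect_spikes()] result (or numeric spike times).
#' @return Successive differences of the spike times (s).
#' @export
interspike_intervals <- function(train) {
  times <- if (inherits(train, "spike_train")) train$times else train
  if (length(times) < 2L)
    stop("interspike_intervals: need at least 2 spikes")
  diff(times)
}

#' Adaptation index of an ISI sequence
#'
#' `(last - first) / (last + first)`: 0 for constant intervals, positive
#' when firing slows down, negative when it speeds up; bounded in
#' (-1, 1).
#'
#' @param isis interspike intervals (s), at least 2.
#' @return Dimensionless adaptation index.
#' @export
adaptation_index <- function(isis) {
  if (length(isis) < 2L) stop("adaptation_index: need at least 2 ISIs")
  (isis[length(isis)] - isis[1L]) / (isis[length(isis)] + isis[1L])
}

#' Detect bursts in a spike train
#'
#' A burst is a maximal group of at least two spikes whose internal gaps
#' are all `<= isi_intra`, separated from neighboring spikes by at least
#' `isi_inter`. Singleton spikes never form bursts.
#'
#' @param train a `spike_train` or numeric spike times.
#' @param isi_intra maximum within-burst interval (s).
#' @param isi_inter minimum separation from spikes outside the burst (s).
#' @return List of bursts, each a numeric vector of spike times.
#' @export
detect_bursts <- function(train, isi_intra = 3e-3, isi_inter = 1.5e-2) {
  if (isi_intra >= isi_inter)
    stop("detect_bursts: need isi_intra < isi_inter")
  times <- if (inherits(train, "spike_train")) train$times else train
  n <- length(times)
  if (n == 0L) return(list())
  gaps <- if (n > 1L) diff(times) else numeric(0)
  grp <- cumsum(c(1L, as.integer(gaps > isi_intra)))
  groups <- split(times, grp)
  out <- list()
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    if (length(g) < 2L) next
    ok_before <- k == 1L ||
      g[1L] - max(groups[[k - 1L]]) >= isi_inter
    ok_after <- k == length(groups) ||
      min(groups[[k + 1L]]) - g[length(g)] >= isi_inter
    if (ok_before && ok_after) out[[length(out) + 1L]] <- g
  }
  out
}

#' First-spike latency
#'
#' @param train a `spike_train` or numeric spike times.
#' @param t_on stimulus onset (s).
#' @return Time from onset to the first spike at or after it (s).
#' @export
latency <- function(train, t_on) {
  times <- if (inherits(train, "spike_train")) train$times else train
  times <- times[times >= t_on]
  if (!length(times)) stop("latency: no spike after stimulus onset")
  times[1L] - t_on
}

#' f-I curve of a circuit
#'
#' Simulates a sustained step at each amplitude and measures the
#' steady-state firing frequency over the second half of the window:
#' `(n - 1) / (t_last - t_first)` among the spikes there, or 0 when fewer
#' than two spikes fall in it.
#'
#' @param object a [ucn_circuit()].
#' @param amplitudes step amplitudes (A), sorted ascending.
#' @param duration window length (s); should be much longer than the
#'   membrane time constant.
#' @param negative use negative steps (for the inhibitory variant).
#' @param ... passed to [simulate.ucn_circuit()].
#' @return Data frame with columns `amplitude` (A) and `frequency` (Hz),
#'   of class `"fi_curve"`.
#' @export
f_i_curve <- function(object, amplitudes, duration, negative = FALSE, ...) {
  if (is.unsorted(amplitudes))
    stop("f_i_curve: amplitudes must be sorted ascending")
  freq <- vapply(amplitudes, function(a) {
    stim <- if (negative) stimulus("negative_step", t_on = 0, amplitude = a)
            else stimulus("step", t_on = 0, amplitude = a)
    tr <- tryCatch(simulate(object, stimulus = stim, t_end = duration, ...),
                   error = function(e)
                     stop("f_i_curve: simulation failed at amplitude ", a,
                          ": ", conditionMessage(e)))
    st <- event_times(tr)
    st <- st[st >= duration / 2]
    if (length(st) < 2L) 0 else (length(st) - 1) / (st[length(st)] - st[1L])
  }, numeric(1))
  structure(data.frame(amplitude = amplitudes, frequency = freq),
            class = c("fi_curve", "data.frame"))
}

#' Classify excitability class from an f-I curve
#'
#' Class 1: the firing frequency grows continuously from zero, detected
#' as a smallest nonzero frequency below `f_eps`. Class 2: the frequency
#' jumps discontinuously from 0 to at least `f_jump` between adjacent
#' amplitudes. A curve without both zero and nonzero entries is
#' unclassified.
#'
#' @param fi an [f_i_curve()] result (or data frame with a `frequency`
#'   column).
#' @param f_eps class-1 continuity bound (Hz).
#' @param f_jump class-2 jump size (Hz).
#' @return `"class1_excitable"`, `"class2_excitable"` or
#'   `"unclassified"`.
#' @export
classify_excitability <- function(fi, f_eps = 25, f_jump = 100) {
  f <- fi$frequency
  nz <- f[f > 0]
  if (!length(nz) || !any(f == 0)) return("unclassified")
  if (min(nz) < f_eps) return("class1_excitable")
  jumps <- which(f[-length(f)] == 0 & f[-1L] >= f_jump)
  if (length(jumps)) return("class2_excitable")
  "unclassified"
}

#' Classifier rule thresholds
#'
#' Windows are expressed through the membrane time constant `tau`;
#' defaults follow the millisecond-scale canonical circuit.
#'
#' @param tau membrane time constant (s).
#' @param v_half spike detection level (V); `NULL` for automatic.
#' @param t_refractory spike merge window (s).
#' @param isi_intra,isi_inter burst grouping thresholds (s).
#' @param ai_tonic maximum `|adaptation index|` for tonic firing.
#' @param ai_adapt minimum adaptation index for spike-frequency
#'   adaptation.
#' @param n_tonic minimum spike count for sustained firing.
#' @param span_tonic fraction of the stimulus that tonic firing must
#'   cover.
#' @param onset_window phasic / rebound window, in units of `tau`.
#' @param latency_factor spike latency must exceed this multiple of the
#'   tonic-reference latency `tau * log(3)` (the first-spike latency at
#'   1.5 times the rheobase drive).
#' @param f_eps,f_jump excitability-class thresholds (Hz).
#' @return A list of rule thresholds.
#' @export
behavior_rules <- function(tau = 1e-2, v_half = NULL, t_refractory = 2e-4,
                           isi_intra = 3e-3, isi_inter = 1.5e-2,
                           ai_tonic = 0.1, ai_adapt = 0.15, n_tonic = 5L,
                           span_tonic = 0.8, onset_window = 5,
                           latency_factor = 3, f_eps = 25, f_jump = 100) {
  list(tau = tau, v_half = v_half, t_refractory = t_refractory,
       isi_intra = isi_intra, isi_inter = isi_inter, ai_tonic = ai_tonic,
       ai_adapt = ai_adapt, n_tonic = n_tonic, span_tonic = span_tonic,
       onset_window = onset_window, latency_factor = latency_factor,
       f_eps = f_eps, f_jump = f_jump)
}

#' The recognised behavior labels
#' @return Character vector of all labels the classifier can emit.
#' @export
behavior_labels <- function() {
  c("tonic_spiking", "phasic_spiking", "phasic_bursting", "mixed",
    "spike_frequency_adaptation", "class1_excitable", "class2_excitable",
    "spike_latency", "integrator", "accommodation", "rebound_spike",
    "inhibition_induced_spiking", "silent", "unclassified")
}

#' Classify a (stimulus, trace) pair into a behavior label
#'
#' Applies a fixed-order predicate table. Negative-polarity stimuli are
#' routed to the rebound / inhibition predicates, ramp-then-step to the
#' accommodation predicate; all other stimuli run the positive ladder
#' tonic, phasic spiking, phasic bursting, mixed, spike-frequency
#' adaptation, spike latency. The classifier is total: it returns
#' `"silent"` for a spike-free trace and `"unclassified"` when no
#' predicate matches. Multi-run behaviors (integrator, accommodation as
#' two runs, excitability classes) are handled at the scenario level by
#' [run_scenario()].
#'
#' @param trace a `ucn_trace`.
#' @param stim the [stimulus()] that produced it.
#' @param rules a [behavior_rules()] list.
#' @return A single label from [behavior_labels()].
#' @export
classify_behavior <- function(trace, stim = attr(trace, "stimulus"),
                              rules = NULL) {
  stopifnot(inherits(stim, "ucn_stimulus"))
  if (is.null(rules)) {
    sys <- attr(trace, "system")
    rules <- behavior_rules(tau = if (!is.null(sys)) ucn_tau(sys) else 1e-2)
  }
  train <- detect_spikes(trace, v_half = rules$v_half,
                         t_refractory = rules$t_refractory)
  times <- train$times
  n <- length(times)
  if (n == 0L) return("silent")
  tau <- rules$tau
  t_on <- stim$t_on
  t_end <- trace$t[nrow(trace)]
  win <- rules$onset_window * tau

  if (stim$kind == "negative_pulse") {
    t_off <- t_on + stim$width
    during <- times[times >= t_on & times < t_off]
    after <- times[times >= t_off & times <= t_off + win]
    if (!length(during) && length(after) >= 1L) return("rebound_spike")
    if (length(during) >= rules$n_tonic) return("inhibition_induced_spiking")
    return("unclassified")
  }
  if (stim$kind == "negative_step") {
    if (sum(times >= t_on) >= rules$n_tonic)
      return("inhibition_induced_spiking")
    return("unclassified")
  }
  if (stim$kind == "ramp_then_step") {
    pre_step <- times[times < stim$t_step]
    at_step <- times[times >= stim$t_step & times <= stim$t_step + win]
    if (!length(pre_step) && length(at_step) >= 1L) return("accommodation")
    return("unclassified")
  }

  stim_dur <- t_end - t_on
  if (stim$kind == "pulse_train")
    stim_dur <- (stim$count - 1) * stim$period + stim$width
  isis <- if (n >= 2L) diff(times) else numeric(0)
  ai <- if (n >= 3L) adaptation_index(isis) else NA_real_
  bursts <- detect_bursts(times, rules$isi_intra, rules$isi_inter)
  burst_spikes <- unlist(bursts)

  # tonic: sustained regular firing spanning the stimulus
  if (n >= rules$n_tonic && !length(bursts) && !is.na(ai) &&
      abs(ai) < rules$ai_tonic &&
      (times[n] - t_on) > rules$span_tonic * stim_dur)
    return("tonic_spiking")
  # phasic spiking: a single onset spike
  if (n == 1L && times[1L] - t_on <= win)
    return("phasic_spiking")
  # phasic bursting: one onset burst and nothing else
  if (length(bursts) == 1L && length(burst_spikes) == n &&
      bursts[[1L]][1L] - t_on <= win)
    return("phasic_bursting")
  # mixed: an onset burst followed by sustained single spikes
  if (length(bursts) >= 1L && bursts[[1L]][1L] - t_on <= win &&
      sum(times > max(burst_spikes)) >= 3L)
    return("mixed")
  # spike-frequency adaptation: monotone ISI lengthening
  if (n >= rules$n_tonic && length(isis) >= 2L && all(diff(isis) > 0) &&
      !is.na(ai) && ai >= rules$ai_adapt)
    return("spike_frequency_adaptation")
  # spike latency: delayed response to a sustained input
  if (times[1L] - t_on > rules$latency_factor * tau * log(3))
    return("spike_latency")
  "unclassified"
}
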