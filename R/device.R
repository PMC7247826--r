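#' SCR (thyristor) device parameters
#'
#' Phenomenological description of a silicon controlled rectifier used as the
#' firing element of the ultra-compact neuron: a hysteretic two-state
#' conductor. In the blocking state the device is a large resistance
#' `r_off`; once the anode-cathode voltage reaches the (gate-modulated)
#' breakover threshold it switches to a conducting branch, a small
#' resistance `r_on` in series with a forward drop `v_on`, and it stays
#' there until the anode current falls to the holding current `i_hold`.
#' Gate drive lowers the effective breakover threshold linearly, clamped at
#' `v_th_min` (see [effective_threshold()]).
#'
#' Defaults are canonical engineering choices for a millisecond-scale
#' discrete circuit; every value can be overridden per scenario.
#'
#' @param v_th0 breakover threshold at zero gate drive (V).
#' @param v_th_min threshold floor under maximal gate drive (V).
#' @param alpha_gate threshold reduction per volt of gate drive (V/V).
#' @param i_hold holding current (A).
#' @param r_off blocking-state resistance (ohm).
#' @param r_on conducting-state resistance (ohm).
#' @param v_on forward drop of the conducting branch (V).
#' @return An object of class `"scr_params"`.
#' @seealso [scr_current()], [scr_next_state()], [axon_params()]
#' @examples
#' p <- scr_params()
#' scr_current(scr_state(FALSE), 1, p)   # blocking: 1 V / r_off
#' @export
scr_params <- function(v_th0 = 2, v_th_min = 0.5, alpha_gate = 0.5,
                       i_hold = 1e-5, r_off = 1e7, r_on = 10, v_on = 0.8) {
  p <- list(v_th0 = v_th0, v_th_min = v_th_min, alpha_gate = alpha_gate,
            i_hold = i_hold, r_off = r_off, r_on = r_on, v_on = v_on)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("scr_params: '", nm, "' must be a single finite number")
  }
  if (p$v_th_min <= 0 || p$v_th_min > p$v_th0)
    stop("scr_params: need 0 < v_th_min <= v_th0")
  if (p$r_on >= p$r_off) stop("scr_params: need r_on < r_off")
  if (p$i_hold <= 0) stop("scr_params: need i_hold > 0")
  if (p$v_on < 0) stop("scr_params: need v_on >= 0")
  if (p$alpha_gate < 0) stop("scr_params: need alpha_gate >= 0")
  structure(p, class = "scr_params")
}

#' SCR discrete state
#'
#' @param conducting logical; `TRUE` for the low-resistance branch.
#' @param last_switch_time time of the last switching event (s);
#'   `-Inf` for a device that has never switched.
#' @return An object of class `"scr_state"`.
#' @export
scr_state <- function(conducting = FALSE, last_switch_time = -Inf) {
  stopifnot(is.logical(conducting), length(conducting) == 1L,
            !is.na(conducting), is.numeric(last_switch_time))
  structure(list(conducting = conducting,
                 last_switch_time = last_switch_time),
            class = "scr_state")
}

#' Axon stage parameters
#'
#' The two-transistor axon block of the UCN only strengthens (and
#' re-inverts) the current pulse fired by the SCR; it is idealized as a
#' memoryless comparator on the anode current.
#'
#' @param i_trigger anode current above which the output pulse is high (A).
#' @param v_pulse output high level (V).
#' @return An object of class `"axon_params"`.
#' @export
axon_params <- function(i_trigger = 1e-3, v_pulse = 5) {
  if (!is.numeric(i_trigger) || length(i_trigger) != 1L || i_trigger <= 0)
    stop("axon_params: need i_trigger > 0")
  if (!is.numeric(v_pulse) || length(v_pulse) != 1L || v_pulse <= 0)
    stop("axon_params: need v_pulse > 0")
  structure(list(i_trigger = i_trigger, v_pulse = v_pulse),
            class = "axon_params")
}

## branch current given the discrete branch only; reverse bias blocks with
## r_off in both states (diode-like)
scr_current_num <- function(conducting, v_ak, params) {
  i <- v_ak / params$r_off
  if (conducting) {
    pos <- v_ak >= 0
    i[pos] <- pmax(0, v_ak[pos] - params$v_on) / params$r_on
  }
  i
}

#' Anode current of the SCR
#'
#' Blocking: `v_ak / r_off`. Conducting: `max(0, v_ak - v_on) / r_on`.
#' Under reverse bias (`v_ak < 0`) the device blocks with `r_off` in both
#' states. Vectorized over `v_ak`.
#'
#' @param state an [scr_state()] (or a logical `conducting` flag).
#' @param v_ak anode-cathode voltage (V).
#' @param params an [scr_params()] object.
#' @return Anode current (A), same length as `v_ak`.
#' @export
scr_current <- function(state, v_ak, params) {
  conducting <- if (is.logical(state)) state else state$conducting
  if (!is.numeric(v_ak) || any(!is.finite(v_ak)))
    stop("scr_current: v_ak must be finite")
  scr_current_num(isTRUE(conducting), v_ak, params)
}

#' Effective breakover threshold under gate drive
#'
#' Gate drive lowers the anode-cathode breakover threshold linearly,
#' `v_th0 - alpha_gate * v_gate_drive`, clamped to `[v_th_min, v_th0]`.
#' Monotone non-increasing in the gate drive.
#'
#' @param v_gate_drive non-negative gate drive (V). Vectorized.
#' @param params an [scr_params()] object.
#' @return Effective threshold (V).
#' @export
effective_threshold <- function(v_gate_drive, params) {
  if (!is.numeric(v_gate_drive) || any(!is.finite(v_gate_drive)) ||
      any(v_gate_drive < 0))
    stop("effective_threshold: v_gate_drive must be finite and >= 0")
  pmin(params$v_th0,
       pmax(params$v_th_min, params$v_th0 - params$alpha_gate * v_gate_drive))
}

#' Discrete transition of the SCR state
#'
#' Pure transition function: blocking switches to conducting when `v_ak`
#' reaches the effective threshold; conducting switches back to blocking
#' when the anode current falls to the holding current. Otherwise the state
#' is returned unchanged (the switch time is only updated on a transition).
#'
#' @param state an [scr_state()].
#' @param v_ak anode-cathode voltage (V).
#' @param i_ak anode current (A).
#' @param v_gate_drive gate drive (V), lowers the threshold.
#' @param t current time (s).
#' @param params an [scr_params()] object.
#' @return The next [scr_state()].
#' @export
scr_next_state <- function(state, v_ak, i_ak, v_gate_drive = 0, t = 0,
                           params) {
  if (!state$conducting) {
    if (v_ak >= effective_threshold(v_gate_drive, params))
      return(scr_state(TRUE, t))
  } else {
    if (i_ak <= params$i_hold)
      return(scr_state(FALSE, t))
  }
  state
}

#' Axon output voltage
#'
#' Memoryless comparator: the output is `v_pulse` while the SCR anode
#' current is at least `i_trigger`, otherwise 0. Vectorized over `i_ak`.
#'
#' @param i_ak anode current (A).
#' @param params an [axon_params()] object.
#' @return Output voltage (V).
#' @export
axon_output <- function(i_ak, params) {
  ifelse(i_ak >= params$i_trigger, params$v_pulse, 0)
}

#' Quasi-static I-V sweep of the SCR
#'
#' Steps the anode-cathode voltage through `v_seq`, applying the discrete
#' transition rule at each point, and records the branch current. Sweeping
#' up past the threshold and back down traces the hysteresis loop: the
#' conducting branch persists until the current falls to `i_hold`.
#'
#' @param params an [scr_params()] object.
#' @param v_seq voltage sequence (V), e.g. a triangular up-down sweep.
#' @param v_gate_drive constant gate drive (V).
#' @return A data frame with columns `v`, `i`, `conducting`.
#' @export
sweep_iv <- function(params, v_seq, v_gate_drive = 0) {
  st <- scr_state(FALSE)
  n <- length(v_seq)
  i_out <- numeric(n)
  cond <- logical(n)
  for (k in seq_len(n)) {
    v <- v_seq[k]
    i_now <- scr_current_num(st$conducting, v, params)
    st <- scr_next_state(st, v, i_now, v_gate_drive, t = k, params = params)
    i_out[k] <- scr_current_num(st$conducting, v, params)
    cond[k] <- st$conducting
  }
  data.frame(v = v_seq, i = i_out, conducting = cond)
}

#' @export
print.scr_params <- function(x, ...) {
  cat("SCR device parameters\n")
  cat(sprintf("  breakover threshold : %g V (floor %g V, gate slope %g V/V)\n",
              x$v_th0, x$v_th_min, x$alpha_gate))
  cat(sprintf("  holding current     : %g A\n", x$i_hold))
  cat(sprintf("  resistances         : r_off %g ohm, r_on %g ohm, drop %g V\n",
              x$r_off, x$r_on, x$v_on))
  invisible(x)
}
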