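#' Passive circuit parameters of a UCN variant
#'
#' Component values of the membrane node and the optional input/feedback
#' networks around the SCR. SI units throughout.
#'
#' @param c1 membrane capacitor (F); the integrator of the LIF block.
#' @param r_leak leak resistor (ohm); `tau = r_leak * c1` is the membrane
#'   time constant.
#' @param r_in series input resistor (ohm); for variants with a voltage
#'   input network the stimulus amplitude `a` (A) maps to a source voltage
#'   `a * r_in`.
#' @param c_in series input (differentiator) capacitor (F); 0 disables the
#'   capacitive input path.
#' @param r_dc parallel DC input resistor (ohm); `Inf` disables the DC path.
#' @param c_fb,r_fb feedback network (F, ohm); the feedback variable decays
#'   with `tau_fb = r_fb * c_fb`.
#' @param beta_fb per-spike increment of the feedback variable (V of gate
#'   drive per output pulse); 0 disables the feedback.
#' @param g_shunt adaptation shunt conductance per volt of the feedback
#'   variable (S/V).
#' @param polarity `+1` (excitatory) or `-1` (inhibitory topology).
#' @return An object of class `"circuit_params"`.
#' @export
circuit_params <- function(c1 = 1e-8, r_leak = 1e6, r_in = 1e4, c_in = 0,
                           r_dc = Inf, c_fb = 1e-8, r_fb = 6e6,
                           beta_fb = 0, g_shunt = 0, polarity = 1) {
  p <- list(c1 = c1, r_leak = r_leak, r_in = r_in, c_in = c_in, r_dc = r_dc,
            c_fb = c_fb, r_fb = r_fb, beta_fb = beta_fb, g_shunt = g_shunt,
            polarity = polarity)
  for (nm in names(p))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]))
      stop("circuit_params: '", nm, "' must be a single number")
  if (p$c1 <= 0 || p$r_leak <= 0 || p$r_in <= 0)
    stop("circuit_params: need c1 > 0, r_leak > 0, r_in > 0")
  if (p$c_in < 0 || p$r_dc <= 0 || p$c_fb <= 0 || p$r_fb <= 0 ||
      p$beta_fb < 0 || p$g_shunt < 0)
    stop("circuit_params: optional elements must be non-negative")
  if (!p$polarity %in% c(-1, 1))
    stop("circuit_params: polarity must be +1 or -1")
  structure(p, class = "circuit_params")
}

#' Compile a UCN circuit variant into a hybrid system
#'
#' Each variant couples the membrane node (capacitor `c1`, leak `r_leak`,
#' SCR) to a different input or feedback network:
#' \describe{
#'   \item{`base`}{the plain LIF block; the stimulus is a current source
#'     into the membrane node. Continuous state: `v_mem`.}
#'   \item{`phasic`}{a series-capacitor (differentiator) input network;
#'     the stimulus maps to a source voltage `u * r_in` driving the
#'     membrane through `r_in` and `c_in`. States: `v_mem`, `v_cin`.}
#'   \item{`mixed`}{the differentiator plus a parallel DC path `r_dc`.
#'     States: `v_mem`, `v_cin`.}
#'   \item{`adaptive`}{the base block plus a spike-triggered feedback
#'     variable `w_fb` that drives the SCR gate (lowering the effective
#'     threshold by `alpha_gate * w_fb`) and shunts the membrane with
#'     conductance `g_shunt * w_fb`. `w_fb` jumps by `beta_fb` at each
#'     spike and decays with `r_fb * c_fb`. States: `v_mem`, `w_fb`.}
#'   \item{`inhibitory`}{the mirrored (swapped-polarity) topology excited
#'     by negative input; implemented as a sign convention: the internal
#'     state obeys the base equations driven by `-u`, and the reported
#'     membrane voltage is sign-flipped. State: `v_mem`.}
#' }
#'
#' The hybrid system has one discrete state, the SCR branch. Its two
#' switching events are the threshold crossing (blocking to conducting,
#' the spike) and the holding-current crossing (conducting to blocking).
#'
#' @param variant one of `"base"`, `"phasic"`, `"mixed"`, `"adaptive"`,
#'   `"inhibitory"`.
#' @param circuit a [circuit_params()] object.
#' @param scr an [scr_params()] object.
#' @param axon an [axon_params()] object.
#' @return An object of class `"ucn_circuit"` with fields `variant`,
#'   `circuit`, `scr`, `axon`, `states` (continuous state names) and
#'   `n_events` (always 2).
#' @examples
#' sys <- ucn_circuit("base")
#' sys
#' @export
ucn_circuit <- function(variant = c("base", "phasic", "mixed", "adaptive",
                                    "inhibitory"),
                        circuit = circuit_params(), scr = scr_params(),
                        axon = axon_params()) {
  variant <- match.arg(variant)
  stopifnot(inherits(circuit, "circuit_params"),
            inherits(scr, "scr_params"), inherits(axon, "axon_params"))
  if (variant %in% c("phasic", "mixed") && circuit$c_in <= 0)
    stop("ucn_circuit: variant '", variant,
         "' requires the input capacitor c_in > 0")
  if (variant == "mixed" && !is.finite(circuit$r_dc))
    stop("ucn_circuit: variant 'mixed' requires a finite DC path r_dc")
  if (variant == "adaptive" && circuit$beta_fb <= 0)
    stop("ucn_circuit: variant 'adaptive' requires the feedback increment",
         " beta_fb > 0")
  if (variant == "inhibitory") {
    circuit$polarity <- -1
  } else if (circuit$polarity != 1) {
    stop("ucn_circuit: polarity -1 is only valid for the inhibitory variant")
  }
  states <- switch(variant,
                   base = "v_mem",
                   inhibitory = "v_mem",
                   phasic = c("v_mem", "v_cin"),
                   mixed = c("v_mem", "v_cin"),
                   adaptive = c("v_mem", "w_fb"))
  structure(list(variant = variant, circuit = circuit, scr = scr,
                 axon = axon, states = states, n_events = 2L),
            class = "ucn_circuit")
}

## Branch currents at the membrane node, in the internal (mirror-corrected)
## frame: y and u_int are the internal state and drive; for the inhibitory
## variant both equal -1 times their physical counterparts.
## Returns currents (A) flowing INTO the membrane node as positive.
ucn_branch_currents <- function(object, t, y, u_int, conducting) {
  cc <- object$circuit
  v <- y[1L]
  cur <- list(i_leak = -v / cc$r_leak,
              i_scr = -scr_current_num(conducting, v, object$scr))
  if (object$variant %in% c("phasic", "mixed")) {
    v_src <- u_int * cc$r_in
    i_c <- (v_src - y[2L] - v) / cc$r_in
    cur$i_in <- i_c
    cur$i_cin_branch <- i_c
    if (is.finite(cc$r_dc)) cur$i_dc <- (v_src - v) / cc$r_dc
  } else {
    cur$i_in <- u_int
  }
  if (object$variant == "adaptive")
    cur$i_shunt <- -cc$g_shunt * max(y[2L], 0) * v
  cur
}

#' Time derivatives of the continuous states
#'
#' The membrane equation is charge balance at the membrane node:
#' `c1 * dv_mem/dt` equals the signed sum of the branch currents (input,
#' leak, SCR and, for the adaptive variant, the feedback shunt). Auxiliary
#' states are the input-capacitor voltage (`dv_cin/dt = i_cin / c_in`) and
#' the feedback variable (`dw_fb/dt = -w_fb / (r_fb * c_fb)`).
#'
#' Exposed mainly for validation against closed-form RC solutions; the
#' integrator calls the same internals.
#'
#' @param object a [ucn_circuit()].
#' @param t time (s).
#' @param y continuous state vector, in the order of `object$states`
#'   (internal frame; see the inhibitory note in [ucn_circuit()]).
#' @param u stimulus value (A), physical sign.
#' @param conducting logical SCR branch.
#' @return Named list with `dy` (state rates) and `currents` (branch
#'   currents into the membrane node, A).
#' @export
membrane_derivative <- function(object, t, y, u, conducting = FALSE) {
  if (any(!is.finite(y))) stop("membrane_derivative: non-finite state")
  cc <- object$circuit
  u_int <- cc$polarity * u
  cur <- ucn_branch_currents(object, t, y, u_int, conducting)
  node <- cur$i_in + cur$i_leak + cur$i_scr
  if (!is.null(cur$i_dc)) node <- node + cur$i_dc
  if (!is.null(cur$i_shunt)) node <- node + cur$i_shunt
  dy <- numeric(length(y))
  dy[1L] <- node / cc$c1
  if (object$variant %in% c("phasic", "mixed"))
    dy[2L] <- cur$i_cin_branch / cc$c_in
  if (object$variant == "adaptive")
    dy[2L] <- -y[2L] / (cc$r_fb * cc$c_fb)
  list(dy = dy, currents = cur)
}

## gate drive seen by the SCR (adaptive variant only)
ucn_gate_drive <- function(object, y) {
  if (object$variant == "adaptive") max(y[2L], 0) else 0
}

#' Membrane time constant of a circuit
#'
#' @param object a [ucn_circuit()] (or [circuit_params()]).
#' @return `r_leak * c1` in seconds.
#' @export
ucn_tau <- function(object) {
  cc <- if (inherits(object, "ucn_circuit")) object$circuit else object
  cc$r_leak * cc$c1
}

#' @export
print.ucn_circuit <- function(x, ...) {
  cat(sprintf("UCN circuit, variant '%s'\n", x$variant))
  cat(sprintf("  continuous states : %s\n", paste(x$states, collapse = ", ")))
  cat(sprintf("  membrane tau      : %g s (c1 %g F, r_leak %g ohm)\n",
              ucn_tau(x), x$circuit$c1, x$circuit$r_leak))
  cat(sprintf("  SCR threshold     : %g V, holding current %g A\n",
              x$scr$v_th0, x$scr$i_hold))
  if (x$circuit$polarity < 0) cat("  polarity          : inhibitory (-1)\n")
  invisible(x)
}

#' @export
summary.ucn_circuit <- function(object, ...) {
  print(object)
  th_drive <- object$scr$v_th0 / object$circuit$r_leak
  cat(sprintf("  rheobase drive    : %g A (sustained current at threshold)\n",
              th_drive))
  invisible(object)
}
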