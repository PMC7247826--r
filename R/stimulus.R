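#' Deterministic stimulus waveforms
#'
#' Builds the input current waveform `u(t)` driving a circuit, emulating
#' the current excitation traces used in spiking-behavior studies. All
#' waveforms are zero before `t_on`, piecewise constant or piecewise
#' linear, and deterministic. Amplitudes follow the current-source
#' convention (amperes); circuit variants with a voltage input network
#' convert via their series input resistor.
#'
#' Kinds and their parameters:
#' \describe{
#'   \item{`step`}{sustained step of `amplitude` from `t_on`.}
#'   \item{`pulse_train`}{`count` rectangular pulses of `amplitude` and
#'     `width`, one per `period`, starting at `t_on`.}
#'   \item{`paired_pulse`}{two pulses of `amplitude` and `width` separated
#'     by `gap` (end of first to start of second).}
#'   \item{`ramp`}{linear rise from 0 to `amplitude` over `rise`, then hold.}
#'   \item{`ramp_then_step`}{linear rise to `amplitude` over `rise`, hold
#'     for `hold`, return to 0, then an abrupt step to the same
#'     `amplitude` at `t_step` lasting `width`.}
#'   \item{`negative_step`}{sustained step to `-|amplitude|`.}
#'   \item{`negative_pulse`}{rectangular pulse to `-|amplitude|` of `width`.}
#' }
#'
#' Waveforms are right-continuous: a segment with value `A` on
#' `[t0, t1)` evaluates to `A` at `t0` and to the next value at `t1`.
#'
#' @param kind one of the kinds above.
#' @param t_on onset time (s).
#' @param amplitude amplitude (A); magnitude for the negative kinds.
#' @param width pulse width (s).
#' @param period pulse period (s).
#' @param count number of pulses.
#' @param gap gap between the paired pulses (s).
#' @param rise ramp rise time (s).
#' @param hold hold time at the ramp top (s).
#' @param t_step onset of the abrupt step for `ramp_then_step` (s).
#' @return An object of class `"ucn_stimulus"`.
#' @examples
#' s <- stimulus("step", t_on = 0.01, amplitude = 1e-3)
#' stim_value(s, c(0.005, 0.015))
#' @export
stimulus <- function(kind = c("step", "pulse_train", "paired_pulse", "ramp",
                              "ramp_then_step", "negative_step",
                              "negative_pulse"),
                     t_on = 0, amplitude = NULL, width = NULL, period = NULL,
                     count = NULL, gap = NULL, rise = NULL, hold = 0,
                     t_step = NULL) {
  kind <- match.arg(kind)
  need <- function(val, nm) {
    if (is.null(val) || !is.numeric(val) || length(val) != 1L ||
        !is.finite(val))
      stop("stimulus: kind '", kind, "' requires parameter '", nm, "'")
    val
  }
  if (!is.numeric(t_on) || t_on < 0) stop("stimulus: need t_on >= 0")
  amplitude <- need(amplitude, "amplitude")
  s <- list(kind = kind, t_on = t_on, amplitude = amplitude)
  if (kind %in% c("pulse_train", "paired_pulse", "negative_pulse",
                  "ramp_then_step"))
    s$width <- need(width, "width")
  if (kind == "pulse_train") {
    s$period <- need(period, "period")
    s$count <- need(count, "count")
    if (s$count < 1 || s$count != round(s$count))
      stop("stimulus: count must be a positive integer")
    if (s$period <= s$width)
      stop("stimulus: period must exceed width")
  }
  if (kind == "paired_pulse") s$gap <- need(gap, "gap")
  if (kind %in% c("ramp", "ramp_then_step")) s$rise <- need(rise, "rise")
  if (kind == "ramp_then_step") {
    s$hold <- hold
    s$t_step <- need(t_step, "t_step")
    if (s$t_step < t_on + s$rise + hold)
      stop("stimulus: t_step must come after the ramp returns to zero")
  }
  if (kind %in% c("negative_step", "negative_pulse"))
    s$amplitude <- -abs(amplitude)
  structure(s, class = "ucn_stimulus")
}

#' Evaluate a stimulus waveform
#'
#' @param stim an [stimulus()] object.
#' @param t times (s), vectorized.
#' @return Input current `u(t)` (A).
#' @export
stim_value <- function(stim, t) {
  a <- stim$amplitude
  tt <- t - stim$t_on
  u <- numeric(length(t))
  on <- tt >= 0
  switch(stim$kind,
    step = ,
    negative_step = {
      u[on] <- a
    },
    pulse_train = {
      ph <- tt %% stim$period
      k <- floor(tt / stim$period)
      u[on & ph < stim$width & k < stim$count] <- a
    },
    paired_pulse = {
      in1 <- on & tt < stim$width
      t2 <- stim$width + stim$gap
      in2 <- tt >= t2 & tt < t2 + stim$width
      u[in1 | in2] <- a
    },
    negative_pulse = {
      u[on & tt < stim$width] <- a
    },
    ramp = {
      rising <- on & tt < stim$rise
      u[rising] <- a * tt[rising] / stim$rise
      u[tt >= stim$rise] <- a
    },
    ramp_then_step = {
      rising <- on & tt < stim$rise
      u[rising] <- a * tt[rising] / stim$rise
      top <- tt >= stim$rise & tt < stim$rise + stim$hold
      u[top] <- a
      ts <- stim$t_step - stim$t_on
      u[tt >= ts & tt < ts + stim$width] <- a
    }
  )
  u
}

## times at which u(t) has a kink or jump; integration segments are split
## here so the stepper never sees a discontinuity
stim_breakpoints <- function(stim, t_end) {
  b <- switch(stim$kind,
    step = ,
    negative_step = stim$t_on,
    negative_pulse = c(stim$t_on, stim$t_on + stim$width),
    pulse_train = {
      starts <- stim$t_on + (seq_len(stim$count) - 1L) * stim$period
      c(rbind(starts, starts + stim$width))
    },
    paired_pulse = {
      s2 <- stim$t_on + stim$width + stim$gap
      c(stim$t_on, stim$t_on + stim$width, s2, s2 + stim$width)
    },
    ramp = c(stim$t_on, stim$t_on + stim$rise),
    ramp_then_step = c(stim$t_on, stim$t_on + stim$rise,
                       stim$t_on + stim$rise + stim$hold,
                       stim$t_step, stim$t_step + stim$width)
  )
  sort(unique(b[b > 0 & b < t_end]))
}

#' @export
print.ucn_stimulus <- function(x, ...) {
  extra <- setdiff(names(x), c("kind", "t_on", "amplitude"))
  cat(sprintf("Stimulus '%s': t_on %g s, amplitude %g A", x$kind, x$t_on,
              x$amplitude))
  if (length(extra))
    cat(", ", paste(sprintf("%s %g", extra,
                            unlist(x[extra])), collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}
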