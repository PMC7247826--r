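#' Simulate a UCN circuit through time
#'
#' Integrates the hybrid system: between SCR switching events the
#' continuous states are advanced with a stiff-capable adaptive stepper
#' (`deSolve::lsodar`), whose root finder localizes each event; the
#' discrete transition is then applied exactly once and integration
#' restarts in the new mode. Integration segments are additionally split
#' at the stimulus breakpoints so the stepper never crosses a
#' discontinuity of `u(t)`.
#'
#' The two event functions are the threshold crossing
#' `v_ak - effective_threshold(gate drive)` while blocking, and the
#' holding crossing `i_ak - i_hold` while conducting. At each threshold
#' crossing (the spike) the adaptive variant's feedback variable jumps by
#' `beta_fb`. A minimum dwell time guards against event chattering: if
#' many consecutive events violate it, the simulation aborts with a
#' diagnostic rather than silently coarsening.
#'
#' @param object a [ucn_circuit()].
#' @param nsim,seed accepted for compatibility with the [stats::simulate()]
#'   generic and ignored: the simulator is fully deterministic.
#' @param stimulus an [stimulus()] object.
#' @param t_end end time (s).
#' @param dt_max maximum internal step (s).
#' @param event_tol requested time resolution of event localization (s);
#'   must be smaller than `dt_max`.
#' @param sample_dt sampling grid spacing of the returned trace (s);
#'   default `t_end / 5000`. Event times are always included, duplicated
#'   with the pre- and post-switch discrete state.
#' @param y0 initial continuous state (defaults to rest, all zeros).
#' @param rtol,atol integrator tolerances.
#' @param min_dwell minimum dwell time per discrete mode (s).
#' @param ... unused.
#' @return An object of class `c("ucn_trace", "data.frame")` with columns
#'   `t`, `u` (A), `v_mem` (V), `v_out` (V), `conducting` (0/1), and
#'   attributes `events` (data frame of switch times and directions),
#'   `system`, `stimulus`, `dt_nominal`.
#' @examples
#' sys <- ucn_circuit("base")
#' tr <- simulate(sys, stimulus = stimulus("step", t_on = 0.01,
#'                                         amplitude = 4e-6),
#'                t_end = 0.05)
#' summary(tr)
#' @export
simulate.ucn_circuit <- function(object, nsim = 1, seed = NULL, stimulus,
                                 t_end, dt_max = 1e-4, event_tol = 1e-9,
                                 sample_dt = NULL, y0 = NULL, rtol = 1e-8,
                                 atol = 1e-10, min_dwell = 1e-7, ...) {
  stopifnot(inherits(stimulus, "ucn_stimulus"))
  if (!is.numeric(t_end) || t_end <= 0) stop("simulate: need t_end > 0")
  if (!is.numeric(dt_max) || dt_max <= 0) stop("simulate: need dt_max > 0")
  if (!is.numeric(event_tol) || event_tol <= 0 || event_tol >= dt_max)
    stop("simulate: need 0 < event_tol < dt_max")
  if (is.null(sample_dt)) sample_dt <- t_end / 5000
  ns <- length(object$states)
  if (is.null(y0)) y0 <- numeric(ns)
  if (length(y0) != ns || any(!is.finite(y0)))
    stop("simulate: y0 must be a finite vector of length ", ns)

  scr <- object$scr
  cc <- object$circuit
  stim <- stimulus

  deriv_fun <- function(t, y, parms) {
    list(membrane_derivative(object, t, y,
                             stim_value(stim, t), parms$conducting)$dy)
  }
  root_fun <- function(t, y, parms) {
    if (parms$conducting) {
      scr_current_num(TRUE, y[1L], scr) - scr$i_hold
    } else {
      y[1L] - effective_threshold(ucn_gate_drive(object, y), scr)
    }
  }

  grid <- unique(sort(c(seq(0, t_end, by = sample_dt), t_end,
                        stim_breakpoints(stim, t_end))))
  brks <- c(stim_breakpoints(stim, t_end), t_end)

  t_cur <- 0
  y_cur <- y0
  conducting <- FALSE
  rows_t <- numeric(0)
  rows_y <- NULL
  rows_cond <- logical(0)
  ev_time <- numeric(0)
  ev_dir <- character(0)
  last_switch <- -Inf
  chatter <- 0L

  push <- function(tv, ym, cond) {
    rows_t <<- c(rows_t, tv)
    rows_y <<- rbind(rows_y, ym)
    rows_cond <<- c(rows_cond, rep(cond, length(tv)))
  }
  push(0, matrix(y_cur, nrow = 1L), conducting)

  while (t_cur < t_end - 1e-15 * t_end) {
    t_seg <- brks[brks > t_cur + 1e-15][1L]
    times <- grid[grid > t_cur & grid <= t_seg]
    times <- unique(c(t_cur, times, t_seg))
    # drop samples closer than the stepper can distinguish, keeping both ends
    if (length(times) > 2L) {
      tiny <- 1e-12 * max(t_end, 1)
      times <- times[c(TRUE, diff(times) > tiny)]
      nlast <- length(times)
      if (times[nlast] < t_seg) times[nlast] <- t_seg
      if (nlast >= 2L && times[nlast] - times[nlast - 1L] <= tiny)
        times <- times[-(nlast - 1L)]
    }
    out <- deSolve::lsodar(y = y_cur, times = times, func = deriv_fun,
                           parms = list(conducting = conducting),
                           rootfunc = root_fun, hmax = dt_max,
                           rtol = rtol, atol = atol)
    troot <- attr(out, "troot")
    ymat <- out[, -1L, drop = FALSE]
    if (any(!is.finite(ymat)))
      stop("simulate: non-finite state near t = ", signif(t_cur, 6))
    tvec <- out[, 1L]
    keep <- tvec > t_cur
    push(tvec[keep], ymat[keep, , drop = FALSE], conducting)
    t_last <- tvec[length(tvec)]
    y_last <- ymat[nrow(ymat), ]

    if (!is.null(troot) && length(troot)) {
      t_ev <- troot[1L]
      if (t_ev - last_switch < min_dwell) {
        chatter <- chatter + 1L
        if (chatter >= 100L)
          stop("simulate: event chattering at t = ", signif(t_ev, 8),
               " in mode ", if (conducting) "conducting" else "blocking",
               " (dwell < ", min_dwell, " s repeated)")
      } else chatter <- 0L
      ev_time <- c(ev_time, t_ev)
      if (!conducting) {
        ev_dir <- c(ev_dir, "up")
        conducting <- TRUE
        if (object$variant == "adaptive")
          y_last[2L] <- y_last[2L] + cc$beta_fb
      } else {
        ev_dir <- c(ev_dir, "down")
        conducting <- FALSE
      }
      last_switch <- t_ev
      # duplicated sample: post-switch state at the event time
      push(t_ev, matrix(y_last, nrow = 1L), conducting)
      t_cur <- t_ev
      y_cur <- y_last
    } else {
      t_cur <- t_last
      y_cur <- y_last
    }
  }

  v_mem_int <- rows_y[, 1L]
  i_ak <- scr_current_num(TRUE, v_mem_int, scr)
  i_ak[!rows_cond] <- v_mem_int[!rows_cond] / scr$r_off
  v_out <- ifelse(rows_cond & i_ak >= object$axon$i_trigger,
                  object$axon$v_pulse, 0)
  tr <- data.frame(t = rows_t,
                   u = stim_value(stim, rows_t),
                   v_mem = cc$polarity * v_mem_int,
                   v_out = v_out,
                   conducting = as.integer(rows_cond))
  rownames(tr) <- NULL
  attr(tr, "events") <- data.frame(time = ev_time, direction = ev_dir)
  attr(tr, "system") <- object
  attr(tr, "stimulus") <- stim
  attr(tr, "dt_nominal") <- sample_dt
  class(tr) <- c("ucn_trace", "data.frame")
  tr
}

#' Spike (threshold-crossing) times of a simulated trace
#'
#' Convenience accessor for the exact up-switch event times recorded by
#' the integrator; for detection from the sampled output voltage see
#' [detect_spikes()].
#'
#' @param trace a `ucn_trace`.
#' @return Numeric vector of event times (s).
#' @export
event_times <- function(trace) {
  ev <- attr(trace, "events")
  ev$time[ev$direction == "up"]
}

#' Localize a sign change by bisection
#'
#' Refines a bracketed root of a scalar function of time to a requested
#' time tolerance. Used by the fixed-step reference integrator to place
#' switching events inside a step, and available for dense-output event
#' refinement in general.
#'
#' @param g function of time.
#' @param t_lo,t_hi bracket with `g(t_lo) * g(t_hi) <= 0`.
#' @param tol time tolerance (s).
#' @return Root location `t*` with the bracket refined to width `<= tol`.
#' @examples
#' locate_event(function(t) t - 0.5, 0, 1, 1e-9)
#' @export
locate_event <- function(g, t_lo, t_hi, tol = 1e-9) {
  stopifnot(t_hi > t_lo, tol > 0)
  g_lo <- g(t_lo)
  g_hi <- g(t_hi)
  if (g_lo == 0) return(t_lo)
  if (g_hi == 0) return(t_hi)
  if (g_lo * g_hi > 0)
    stop("locate_event: no sign change on [", t_lo, ", ", t_hi, "]")
  while (t_hi - t_lo > tol) {
    mid <- (t_lo + t_hi) / 2
    g_mid <- g(mid)
    if (g_mid == 0) return(mid)
    if (g_lo * g_mid < 0) {
      t_hi <- mid
    } else {
      t_lo <- mid
      g_lo <- g_mid
    }
  }
  (t_lo + t_hi) / 2
}

#' Fixed-step explicit Euler reference integrator
#'
#' A brute-force reference engine for cross-validating the event-driven
#' integrator: explicit Euler at a fixed step, with switching events
#' placed inside a step by [locate_event()] on the linear interpolant of
#' the event function, after which the remainder of the step is taken in
#' the new mode (the sample grid stays aligned).
#'
#' @param object a [ucn_circuit()].
#' @param stimulus an [stimulus()] object.
#' @param t_end end time (s).
#' @param dt fixed step (s).
#' @param sample_every record every this-many steps (the first and last
#'   samples are always recorded).
#' @param y0 initial state.
#' @return A data frame with columns `t`, `v_mem`, `conducting` at the
#'   recorded samples, with attribute `spike_times` (exact up-switch
#'   times).
#' @export
simulate_euler <- function(object, stimulus, t_end, dt = 1e-7,
                           sample_every = 100L, y0 = NULL) {
  stopifnot(inherits(stimulus, "ucn_stimulus"), t_end > 0, dt > 0)
  ns <- length(object$states)
  if (is.null(y0)) y0 <- numeric(ns)
  scr <- object$scr
  cc <- object$circuit
  base_like <- object$variant %in% c("base", "inhibitory")
  n <- ceiling(t_end / dt)
  tgrid <- (0:n) * dt
  ugrid <- cc$polarity * stim_value(stimulus, tgrid)
  keep <- unique(c(seq(1L, n + 1L, by = sample_every), n + 1L))
  out_v <- numeric(length(keep))
  out_c <- logical(length(keep))
  spike_times <- numeric(0)
  y <- y0
  conducting <- FALSE
  ki <- 1L
  # scalar constants hoisted out of the step loop
  g_leak <- 1 / cc$r_leak
  g_off <- 1 / scr$r_off
  g_on <- 1 / scr$r_on
  inv_c1 <- 1 / cc$c1
  v_on <- scr$v_on
  i_hold <- scr$i_hold
  deriv <- function(t_i, y, u_i, cond) {
    if (base_like) {
      v <- y[1L]
      i_scr <- if (cond && v >= 0) max(0, v - v_on) * g_on else v * g_off
      (u_i - v * g_leak - i_scr) * inv_c1
    } else {
      membrane_derivative(object, t_i, y, cc$polarity * u_i, cond)$dy
    }
  }
  ev_g <- function(y, cond) {
    v <- y[1L]
    if (cond) {
      (if (v >= 0) max(0, v - v_on) * g_on else v * g_off) - i_hold
    } else {
      v - effective_threshold(ucn_gate_drive(object, y), scr)
    }
  }
  v_th_flat <- effective_threshold(0, scr)  # constant unless adaptive
  g_prev <- ev_g(y, conducting)
  for (i in seq_len(n + 1L)) {
    if (ki <= length(keep) && i == keep[ki]) {
      out_v[ki] <- cc$polarity * y[1L]
      out_c[ki] <- conducting
      ki <- ki + 1L
    }
    if (i > n) break
    if (base_like) {
      # inlined scalar step: the reference engine is run for millions of
      # steps, so avoid closure calls on the hot path
      v <- y[1L]
      i_scr <- if (conducting && v >= 0) {
        ov <- v - v_on
        if (ov > 0) ov * g_on else 0
      } else v * g_off
      dy <- (ugrid[i] - v * g_leak - i_scr) * inv_c1
      y_new <- v + dt * dy
      g_new <- if (conducting) {
        ov <- if (y_new >= 0) y_new - v_on else 0
        (if (ov > 0) ov * g_on else if (y_new < 0) y_new * g_off else 0) -
          i_hold
      } else y_new - v_th_flat
    } else {
      dy <- deriv(tgrid[i], y, ugrid[i], conducting)
      y_new <- y + dt * dy
      g_new <- ev_g(y_new, conducting)
    }
    crossed <- if (conducting) g_prev > 0 && g_new <= 0
               else g_prev < 0 && g_new >= 0
    if (crossed) {
      # linear interpolant of the event function across the step
      t_star <- locate_event(function(s) g_prev + (g_new - g_prev) *
                               (s - tgrid[i]) / dt,
                             tgrid[i], tgrid[i] + dt, tol = dt * 1e-6)
      frac <- (t_star - tgrid[i]) / dt
      y_star <- y + frac * dt * dy
      if (!conducting) {
        spike_times <- c(spike_times, t_star)
        conducting <- TRUE
        if (object$variant == "adaptive") y_star[2L] <- y_star[2L] + cc$beta_fb
      } else {
        conducting <- FALSE
      }
      dy2 <- deriv(t_star, y_star, ugrid[i], conducting)
      y_new <- y_star + (1 - frac) * dt * dy2
      g_new <- ev_g(y_new, conducting)
    }
    y <- y_new
    g_prev <- g_new
  }
  res <- data.frame(t = tgrid[keep], v_mem = out_v,
                    conducting = as.integer(out_c))
  attr(res, "spike_times") <- spike_times
  res
}

#' Write / read a trace as CSV
#'
#' Traces are written as plain CSV with header
#' `t,u,v_mem,v_out,conducting` and numbers formatted with 17 significant
#' digits (`%.17g`), which round-trips IEEE doubles exactly; event rows
#' keep their duplication.
#'
#' @param trace a `ucn_trace` (or compatible data frame).
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `ucn_trace` data frame.
#' @export
write_trace <- function(trace, path) {
  cols <- c("t", "u", "v_mem", "v_out", "conducting")
  stopifnot(all(cols %in% names(trace)))
  m <- vapply(cols, function(cn) sprintf("%.17g", trace[[cn]]),
              character(nrow(trace)))
  lines <- c(paste(cols, collapse = ","),
             apply(matrix(m, nrow = nrow(trace)), 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("read_trace: no such file: ", path)
  if (file.size(path) == 0) stop("read_trace: empty file: ", path)
  df <- utils::read.csv(path, colClasses = "numeric")
  cols <- c("t", "u", "v_mem", "v_out", "conducting")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("read_trace: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[cols]
  df$conducting <- as.integer(df$conducting)
  class(df) <- c("ucn_trace", "data.frame")
  df
}

#' @export
print.ucn_trace <- function(x, n = 6L, ...) {
  cat(sprintf("UCN trace: %d samples, t in [%g, %g] s\n", nrow(x),
              x$t[1L], x$t[nrow(x)]))
  ev <- attr(x, "events")
  if (!is.null(ev))
    cat(sprintf("  switching events: %d (%d spikes)\n", nrow(ev),
                sum(ev$direction == "up")))
  print(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' @export
summary.ucn_trace <- function(object, ...) {
  ev <- attr(object, "events")
  cat(sprintf("UCN trace: %d samples over %g s\n", nrow(object),
              object$t[nrow(object)] - object$t[1L]))
  cat(sprintf("  v_mem range : [%g, %g] V\n", min(object$v_mem),
              max(object$v_mem)))
  cat(sprintf("  output pulses high %g%% of the time\n",
              100 * mean(object$v_out > 0)))
  if (!is.null(ev) && nrow(ev))
    cat(sprintf("  %d spikes, first at %g s\n", sum(ev$direction == "up"),
                ev$time[ev$direction == "up"][1L]))
  invisible(object)
}

#' Stacked stimulus / membrane / output plot of a trace
#'
#' Three stacked panels: input current (red), membrane voltage (green),
#' output voltage (blue) -- the conventional presentation of spiking
#' behavior traces.
#'
#' @param x a `ucn_trace`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ucn_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$u, type = "l", col = "red3", xlab = "",
                 ylab = "I_in (A)", ...)
  graphics::plot(x$t, x$v_mem, type = "l", col = "forestgreen", xlab = "",
                 ylab = "V_mem (V)", ...)
  graphics::plot(x$t, x$v_out, type = "l", col = "blue3", xlab = "t (s)",
                 ylab = "V_out (V)", ...)
  invisible(x)
}
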