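#' Heaviside step with the right-continuous convention
#'
#' The single place the convention lives: `heaviside(0) = 1`. This makes
#' the slow-outward saturation `k_inf` continuous at `V_c`; everywhere
#' else the choice is measure-zero.
#'
#' @param x Numeric vector.
#' @return 0/1 numeric vector.
#' @export
heaviside <- function(x) as.numeric(x >= 0)

#' Cell state of the four-current model
#'
#' The five dynamical variables at one point: the dimensionless membrane
#' potential `V` and the four gates `h` (fast-inward inactivation),
#' `f` (slow-inward inactivation), `r` (transient-outward activation),
#' `s` (transient-outward inactivation). The default is the analytic
#' resting state, an exact fixed point of the dynamics.
#'
#' @param V,h,f,r,s Scalar state variables; gates must lie in \[0, 1\].
#' @return A named numeric vector of class `cell_state`.
#' @export
cell_state <- function(V = 0, h = 1, f = 1, r = 0, s = 1) {
  st <- c(V = V, h = h, f = f, r = r, s = s)
  if (any(!is.finite(st))) stop("cell state must be finite")
  if (any(st[-1] < -1e-12) || any(st[-1] > 1 + 1e-12))
    stop("gate variables must lie in [0, 1]")
  structure(st, class = "cell_state")
}

#' Analytic resting state
#' @return The fixed point (V=0, h=1, f=1, r=0, s=1) as a [cell_state()].
#' @export
resting_state <- function() cell_state()

#' Steady-state gate values
#'
#' Piecewise steady states of the gating functions: `m_inf` ramps up
#' above the excitation threshold `V_c`; `h_inf`, `f_inf` step down at
#' `V_c` and `s_inf` at the s-gate threshold; `d_inf` and `fprime_inf`
#' are tanh sigmoids; `k_inf` is linear below `V_c` and saturates at 1
#' above it; `r_inf` steps up at `V_r`.
#'
#' @param V Dimensionless potential (vectorized).
#' @param params An [ap_params()] set.
#' @return A data.frame with columns `m_inf`, `h_inf`, `f_inf`, `s_inf`,
#'   `d_inf`, `fprime_inf`, `k_inf`, `r_inf`.
#' @export
steady_state_gates <- function(V, params) {
  stopifnot(all(is.finite(V)))
  p <- params
  th_c <- heaviside(V - p$V_c)
  v_sw <- if (p$s_gate_threshold == "Vs") p$V_s else p$V_c
  data.frame(
    m_inf = (V - p$V_c) * th_c,
    h_inf = 1 - th_c,
    f_inf = 1 - th_c,
    s_inf = 1 - heaviside(V - v_sw),
    d_inf = th_c * (1 + tanh(p$beta_1 * (V - p$V_1))) / 2,
    fprime_inf = (1 - tanh(p$beta_2 * (V - p$V_2))) / 2,
    k_inf = V / p$V_c + th_c * (1 - V / p$V_c),
    r_inf = heaviside(V - p$V_r))
}

#' Voltage-dependent gate time constants
#'
#' Each gate relaxes exponentially with a two-valued time constant: the
#' "+" value applies on the side of its switching threshold where the
#' steady state is 1, the "-" value on the other side. `tau_h` and
#' `tau_f` switch at `V_c`, `tau_r` at `V_r`, `tau_s` at the s-gate
#' threshold (`V_s` by default).
#'
#' @inheritParams steady_state_gates
#' @return A data.frame with columns `tau_h`, `tau_f`, `tau_r`, `tau_s`
#'   (ms).
#' @export
gate_time_constants <- function(V, params) {
  stopifnot(all(is.finite(V)))
  p <- params
  th_c <- heaviside(V - p$V_c)
  th_r <- heaviside(V - p$V_r)
  v_sw <- if (p$s_gate_threshold == "Vs") p$V_s else p$V_c
  th_s <- heaviside(V - v_sw)
  data.frame(
    tau_h = p$tau_h_plus - (p$tau_h_plus - p$tau_h_minus) * th_c,
    tau_f = p$tau_f_plus - (p$tau_f_plus - p$tau_f_minus) * th_c,
    tau_r = p$tau_r_minus + (p$tau_r_plus - p$tau_r_minus) * th_r,
    tau_s = p$tau_s_plus - (p$tau_s_plus - p$tau_s_minus) * th_s)
}

#' Membrane currents
#'
#' The four scaled transmembrane currents (ms^-1): fast inward
#' `J_fi = -g_fi h m_inf(V) (V_fi - V)` (sodium-like), slow inward
#' `J_si = -g_si d_inf(V) f fprime_inf(V)` (calcium-like, shapes the
#' plateau), slow outward `J_so = g_so k_inf(V)` (potassium-like), and
#' fast transient outward `J_to = g_to r s (V - V_to)` (the notch
#' current). Inward currents are negative; the voltage equation is
#' `dV/dt = -(J_fi + J_si + J_so + J_to) + J_stim`.
#'
#' @param state A [cell_state()] (or named vector with V, h, f, r, s).
#' @param params An [ap_params()] set.
#' @return Named list with `J_fi`, `J_si`, `J_so`, `J_to`.
#' @export
membrane_currents <- function(state, params) {
  ss <- steady_state_gates(state[["V"]], params)
  V <- state[["V"]]
  list(
    J_fi = -params$g_fi * state[["h"]] * ss$m_inf * (params$V_fi - V),
    J_si = -params$g_si * ss$d_inf * state[["f"]] * ss$fprime_inf,
    J_so = params$g_so * ss$k_inf,
    J_to = params$g_to * state[["r"]] * state[["s"]] * (V - params$V_to))
}

#' Time derivative of the cell state
#'
#' Space-clamped right-hand side: the voltage changes by minus the total
#' ionic current plus the stimulus (a positive `J_stim` depolarizes);
#' each gate relaxes toward its voltage-dependent steady state with its
#' voltage-dependent time constant.
#'
#' @inheritParams membrane_currents
#' @param J_stim Stimulus current (ms^-1), depolarizing when positive.
#' @return Named numeric vector of derivatives (V, h, f, r, s).
#' @export
cell_rhs <- function(state, J_stim = 0, params) {
  J <- membrane_currents(state, params)
  ss <- steady_state_gates(state[["V"]], params)
  tau <- gate_time_constants(state[["V"]], params)
  c(V = -(J$J_fi + J$J_si + J$J_so + J$J_to) + J_stim,
    h = (ss$h_inf - state[["h"]]) / tau$tau_h,
    f = (ss$f_inf - state[["f"]]) / tau$tau_f,
    r = (ss$r_inf - state[["r"]]) / tau$tau_r,
    s = (ss$s_inf - state[["s"]]) / tau$tau_s)
}

#' One forward-Euler step of the cell model
#'
#' @inheritParams cell_rhs
#' @param dt Time step (ms), must be positive; the reference value is
#'   0.01 ms.
#' @return Updated [cell_state()].
#' @export
cell_step <- function(state, dt, J_stim = 0, params) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  new <- unclass(state) + dt * cell_rhs(state, J_stim, params)
  structure(new, class = "cell_state")
}

#' Single-cell pacing protocol
#'
#' A train of identical depolarizing current pulses.
#'
#' @param amplitude Pulse amplitude (ms^-1); use
#'   `1.5 * find_stimulus_threshold(params)` for the standard
#'   1.5x-threshold stimulus.
#' @param bcl Basic cycle length (ms) between pulse onsets.
#' @param n_beats Number of pulses.
#' @param duration Pulse duration (ms, default 1).
#' @param start Onset of the first pulse (ms).
#' @return Object of class `cell_protocol`: a data.frame with columns
#'   `t_on`, `t_off`, `amplitude`.
#' @export
cell_pacing <- function(amplitude, bcl = 1000, n_beats = 1, duration = 1,
                        start = 0) {
  stopifnot(duration > 0, n_beats >= 1)
  if (n_beats > 1 && bcl <= duration)
    stop("BCL must exceed the stimulus duration")
  on <- start + (seq_len(n_beats) - 1) * bcl
  structure(data.frame(t_on = on, t_off = on + duration,
                       amplitude = amplitude),
            class = c("cell_protocol", "data.frame"))
}

#' Simulate a space-clamped cell
#'
#' Forward-Euler integration of the four-current model in a single cell,
#' starting from the analytic resting state unless overridden. The
#' recording cadence is decoupled from the integration step.
#'
#' @param params An [ap_params()] set.
#' @param protocol A [cell_pacing()] protocol (or `NULL` for an
#'   unstimulated run).
#' @param duration Total simulated time (ms); defaults to covering the
#'   protocol plus one cycle.
#' @param dt Integration step (ms, default 0.01).
#' @param record_dt Output sampling interval (ms, default 1).
#' @param init Initial [cell_state()].
#' @param record_gates If `TRUE`, include the gate variables in the
#'   output.
#' @return An `ap_trace`: a data.frame with columns `time`, `V` (and
#'   `h`, `f`, `r`, `s` if requested), with the final state in
#'   `attr(, "state")`.
#' @export
simulate_cell <- function(params, protocol = NULL, duration = NULL,
                          dt = 0.01, record_dt = 1,
                          init = resting_state(), record_gates = FALSE) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  ev <- if (is.null(protocol)) {
    matrix(numeric(0), 0, 3)
  } else {
    as.matrix(protocol[, c("t_on", "t_off", "amplitude")])
  }
  if (is.null(duration)) {
    if (nrow(ev) == 0) stop("give `duration` when no protocol is supplied")
    span <- if (nrow(ev) >= 2) diff(ev[1:2, 1]) else 500
    duration <- max(ev[, 2]) + span
  }
  rec_steps <- max(1L, round(record_dt / dt))
  nsteps <- ceiling(duration / dt)
  out <- simulate_cell_cpp(unclass(init), param_vec(params), dt, 0,
                           as.integer(nsteps), ev, as.integer(rec_steps),
                           record_gates)
  tr <- data.frame(time = out$t, V = out$V)
  if (record_gates) {
    g <- out$gates
    tr$h <- g[, 1]; tr$f <- g[, 2]; tr$r <- g[, 3]; tr$s <- g[, 4]
  }
  structure(tr, class = c("ap_trace", "data.frame"),
            state = structure(out$state,
                              names = c("V", "h", "f", "r", "s"),
                              class = "cell_state"),
            dt = dt, params_label = params$label)
}

#' @export
print.ap_trace <- function(x, ...) {
  cat("AP trace [", attr(x, "params_label"), "]: ",
      nrow(x), " samples over ", max(x$time), " ms\n", sep = "")
  cat("V range:", format(range(x$V), digits = 4), "\n")
  invisible(x)
}

#' @export
plot.ap_trace <- function(x, mV = FALSE,
                          convention = voltage_convention(), ...) {
  v <- if (mV) to_millivolts(x$V, convention) else x$V
  plot(x$time, v, type = "l", xlab = "time (ms)",
       ylab = if (mV) "V (mV)" else "V (dimensionless)", ...)
  invisible(x)
}

#' Export a trace as delimited text
#'
#' Two-or-more-column tab-delimited text (`time_ms`, `V`, optionally
#' `V_mV` and gates) with `#`-prefixed header metadata.
#'
#' @param trace An `ap_trace` or probe data.frame.
#' @param path Output file.
#' @param mV Also write a millivolt column.
#' @param convention A [voltage_convention()].
#' @export
write_trace <- function(trace, path, mV = TRUE,
                        convention = voltage_convention()) {
  df <- as.data.frame(trace)
  if (mV && "V" %in% names(df))
    df$V_mV <- to_millivolts(df$V, convention)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fourcurrent trace; params=%s; dt=%s",
                     attr(trace, "params_label") %||% "NA",
                     attr(trace, "dt") %||% "NA"), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
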