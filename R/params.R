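#' Model parameter set for the four-current action potential model
#'
#' Bundles all constants of the four-current membrane model: the paired
#' gate time constants (the "+" value applies while the gate relaxes
#' toward 1, the "-" value while it relaxes toward 0), the four
#' conductances (dimension ms^-1, because the currents are scaled by the
#' membrane capacitance and the 100 mV span), the switching thresholds of
#' the piecewise gate kinetics, and the sigmoid shape constants of the
#' slow inward (calcium-like) current.
#'
#' All potentials are dimensionless: V = (V_mV - V_rest) / 100 mV, so
#' rest is 0 and the plateau is of order 1 (see [voltage_convention()]).
#'
#' @param tau_h_plus,tau_h_minus Fast-inward inactivation gate time
#'   constants (ms).
#' @param tau_f_plus,tau_f_minus Slow-inward inactivation gate time
#'   constants (ms).
#' @param tau_r_plus,tau_r_minus Transient-outward activation gate time
#'   constants (ms).
#' @param tau_s_plus,tau_s_minus Transient-outward inactivation gate time
#'   constants (ms).
#' @param g_fi,g_so,g_si,g_to Conductances of the fast inward, slow
#'   outward, slow inward and transient outward currents (ms^-1).
#'   Zero is allowed (current knockout); negative values are rejected.
#' @param V_fi Reversal potential of the fast inward (sodium-like)
#'   current (dimensionless).
#' @param V_to Reversal potential of the transient outward current
#'   (dimensionless, 0 for all built-in sets).
#' @param V_c Excitation threshold: switching point of the m, h, f gates
#'   and of the slow-outward saturation.
#' @param V_r Switching threshold of the r gate (0.6 for all built-in
#'   sets).
#' @param V_s Switching threshold of the s gate (see `s_gate_threshold`).
#' @param V_1,V_2,beta_1,beta_2 Centers and slopes of the tanh sigmoids
#'   of the slow inward current activation (`d_inf`) and voltage
#'   inactivation (`fprime_inf`).
#' @param label Free-text name of the set.
#' @param s_gate_threshold Either `"Vs"` (default) or `"Vc"`: which
#'   threshold switches the s gate kinetics. `"Vs"` gives `V_s` its
#'   per-cell-type role; `"Vc"` is the literal reading in which the s
#'   gate switches together with h and f.
#'
#' @return An object of class `ap_params` (a validated named list).
#' @seealso [builtin_params()] for the five published sets.
#' @export
ap_params <- function(tau_h_plus, tau_h_minus, tau_f_plus, tau_f_minus,
                      tau_r_plus, tau_r_minus, tau_s_plus, tau_s_minus,
                      g_fi, V_fi, g_so, g_si, beta_1, beta_2, V_1, V_2,
                      g_to, V_c, V_s, V_r = 0.6, V_to = 0,
                      label = "custom",
                      s_gate_threshold = c("Vs", "Vc")) {
  s_gate_threshold <- match.arg(s_gate_threshold)
  p <- list(
    tau_h_plus = tau_h_plus, tau_h_minus = tau_h_minus,
    tau_f_plus = tau_f_plus, tau_f_minus = tau_f_minus,
    tau_r_plus = tau_r_plus, tau_r_minus = tau_r_minus,
    tau_s_plus = tau_s_plus, tau_s_minus = tau_s_minus,
    g_fi = g_fi, V_fi = V_fi, g_so = g_so, g_si = g_si,
    beta_1 = beta_1, beta_2 = beta_2, V_1 = V_1, V_2 = V_2,
    g_to = g_to, V_c = V_c, V_s = V_s, V_r = V_r, V_to = V_to,
    label = label, s_gate_threshold = s_gate_threshold)
  validate_ap_params(p)
  structure(p, class = "ap_params")
}

validate_ap_params <- function(p) {
  taus <- unlist(p[c("tau_h_plus", "tau_h_minus", "tau_f_plus",
                     "tau_f_minus", "tau_r_plus", "tau_r_minus",
                     "tau_s_plus", "tau_s_minus")])
  if (any(!is.finite(taus)) || any(taus <= 0))
    stop("all gate time constants must be finite and > 0", call. = FALSE)
  gs <- unlist(p[c("g_fi", "g_so", "g_si", "g_to")])
  if (any(!is.finite(gs)) || any(gs < 0))
    stop("conductances must be finite and >= 0", call. = FALSE)
  if (!is.finite(p$V_c) || p$V_c <= 0)
    stop("V_c must be > 0", call. = FALSE)
  invisible(p)
}

#' Built-in parameter sets
#'
#' The five published parameter sets of the model: fits to human
#' epicardial, endocardial and midmyocardial cell recordings (Li et al.
#' data), and fits to the TNNP human ventricular and LRd guinea-pig
#' ionic models. All sets share `V_r = 0.6` and `V_to = 0`.
#'
#' @param set One of `"epi"`, `"endo"`, `"mcell"`, `"tnnp"`, `"lrd"`
#'   (case-insensitive).
#' @param ... Passed on to [ap_params()] (e.g. `s_gate_threshold`).
#' @return An `ap_params` object.
#' @examples
#' builtin_params("lrd")
#' @export
builtin_params <- function(set = c("epi", "endo", "mcell", "tnnp", "lrd"),
                           ...) {
  set <- match.arg(tolower(set), c("epi", "endo", "mcell", "tnnp", "lrd"))
  tab <- .param_table[[set]]
  do.call(ap_params, c(tab, list(label = set, ...)))
}

# Published values, one list per column (epi/endo/M from cell
# recordings, tnnp/lrd from model fits).
.param_table <- list(
  epi = list(tau_h_plus = 17.9, tau_h_minus = 11.4,
             tau_f_plus = 123,  tau_f_minus = 183,
             tau_r_plus = 2.51, tau_r_minus = 2.00,
             tau_s_plus = 57.0, tau_s_minus = 10.6,
             g_fi = 4.00, V_fi = 1.46, g_so = 0.0161, g_si = 0.176,
             beta_1 = 3.99, beta_2 = 1.56, V_1 = 0.529, V_2 = 0.386,
             g_to = 2.10, V_c = 0.130, V_s = 0.3),
  endo = list(tau_h_plus = 10.8, tau_h_minus = 10.8,
              tau_f_plus = 355,  tau_f_minus = 52.3,
              tau_r_plus = 7.54, tau_r_minus = 6.07,
              tau_s_plus = 29.1, tau_s_minus = 10.4,
              g_fi = 1.72, V_fi = 1.24, g_so = 0.00891, g_si = 0.414,
              beta_1 = 22.8, beta_2 = 2.95, V_1 = 0.522, V_2 = 0.596,
              g_to = 0.300, V_c = 0.130, V_s = 0.6),
  mcell = list(tau_h_plus = 11.3, tau_h_minus = 1.88,
               tau_f_plus = 101,  tau_f_minus = 228,
               tau_r_plus = 2.15, tau_r_minus = 0.371,
               tau_s_plus = 4.67, tau_s_minus = 1.75,
               g_fi = 2.62, V_fi = 1.60, g_so = 0.0278, g_si = 0.103,
               beta_1 = 27.1, beta_2 = 6.12, V_1 = 0.668, V_2 = 1.08,
               g_to = 1.36, V_c = 0.130, V_s = 0.3),
  tnnp = list(tau_h_plus = 90.5, tau_h_minus = 6.61,
              tau_f_plus = 43.1, tau_f_minus = 181,
              tau_r_plus = 13.5, tau_r_minus = 2.20,
              tau_s_plus = 99.9, tau_s_minus = 4.34,
              g_fi = 14.0, V_fi = 1.18, g_so = 0.0498, g_si = 0.138,
              beta_1 = 11.8, beta_2 = 8.05, V_1 = 0.200, V_2 = 1.02,
              g_to = 9.82, V_c = 0.350, V_s = 0.6),
  lrd = list(tau_h_plus = 25.8, tau_h_minus = 0.950,
             tau_f_plus = 488,  tau_f_minus = 25.4,
             tau_r_plus = 5.10, tau_r_minus = 13.1,
             tau_s_plus = 300,  tau_s_minus = 7.11,
             g_fi = 10.0, V_fi = 1.20, g_so = 0.0316, g_si = 2.32,
             beta_1 = 6.90, beta_2 = 6.36, V_1 = 0.453, V_2 = 0.828,
             g_to = 2.50, V_c = 0.380, V_s = 0.6))

#' Names of the built-in parameter sets
#' @return Character vector.
#' @export
param_sets <- function() names(.param_table)

# Flat numeric vector in the fixed order expected by the C++ kernels.
# Slot 19 ("V_sw") is the threshold actually switching the s gate.
param_vec <- function(params) {
  stopifnot(inherits(params, "ap_params"))
  v_sw <- if (params$s_gate_threshold == "Vs") params$V_s else params$V_c
  c(tau_h_plus = params$tau_h_plus, tau_h_minus = params$tau_h_minus,
    tau_f_plus = params$tau_f_plus, tau_f_minus = params$tau_f_minus,
    tau_r_plus = params$tau_r_plus, tau_r_minus = params$tau_r_minus,
    tau_s_plus = params$tau_s_plus, tau_s_minus = params$tau_s_minus,
    g_fi = params$g_fi, V_fi = params$V_fi, g_so = params$g_so,
    g_si = params$g_si, beta_1 = params$beta_1, beta_2 = params$beta_2,
    V_1 = params$V_1, V_2 = params$V_2, g_to = params$g_to,
    V_c = params$V_c, V_sw = v_sw, V_r = params$V_r, V_to = params$V_to)
}

#' @export
print.ap_params <- function(x, ...) {
  cat("Four-current AP model parameters [", x$label, "]\n", sep = "")
  num <- x[!(names(x) %in% c("label", "s_gate_threshold"))]
  print(unlist(num))
  cat("s gate switches at:", x$s_gate_threshold, "\n")
  invisible(x)
}

#' Update selected entries of a parameter set
#' @param .params An `ap_params` object.
#' @param ... Named scalar replacements (e.g. `g_to = 0`).
#' @return A new validated `ap_params` object.
#' @export
modify_params <- function(.params, ...) {
  stopifnot(inherits(.params, "ap_params"))
  mods <- list(...)
  bad <- setdiff(names(mods), names(.params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  out <- unclass(.params)
  out[names(mods)] <- mods
  validate_ap_params(out)
  structure(out, class = "ap_params")
}

#' Dimensional voltage convention
#'
#' The model works with the dimensionless potential
#' `V = (V_mV - V_rest_mV) / delta_V_mV`; physical millivolts appear only
#' at input/output boundaries through this convention.
#'
#' @param V_rest_mV Resting potential (default -85 mV).
#' @param delta_V_mV Scaling span (default 100 mV).
#' @param C_m Membrane capacitance per unit area (uF cm^-2, default 1).
#' @return Object of class `voltage_convention`.
#' @export
voltage_convention <- function(V_rest_mV = -85, delta_V_mV = 100, C_m = 1) {
  stopifnot(delta_V_mV > 0, C_m > 0)
  structure(list(V_rest_mV = V_rest_mV, delta_V_mV = delta_V_mV, C_m = C_m),
            class = "voltage_convention")
}

#' Convert dimensionless potential to millivolts
#' @param V Dimensionless potential(s).
#' @param convention A [voltage_convention()].
#' @return Numeric vector in mV.
#' @export
to_millivolts <- function(V, convention = voltage_convention()) {
  V * convention$delta_V_mV + convention$V_rest_mV
}

#' Convert millivolts to the dimensionless potential
#' @param V_mV Potential(s) in mV.
#' @inheritParams to_millivolts
#' @return Dimensionless numeric vector.
#' @export
from_millivolts <- function(V_mV, convention = voltage_convention()) {
  (V_mV - convention$V_rest_mV) / convention$delta_V_mV
}
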