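#' Define an AP-template fitting problem
#'
#' Bundles one or more action-potential templates (voltage vs time at a
#' given pacing period), optional conduction-velocity targets, and the
#' weighting scheme. Templates in millivolts are detected by their
#' range and converted with the supplied [voltage_convention()]; the
#' zone after the upstroke that contains the phase-1 notch carries a
#' larger weight, since the notch depth is the feature the transient
#' outward current must capture.
#'
#' @param templates A list; each element is a list or data.frame with
#'   `bcl` (ms) and columns/fields `time` (ms) and `V`.
#' @param cv_targets Optional data.frame with columns `bcl` (ms) and
#'   `cv` (cm/s).
#' @param notch_weight Weight multiplier over the notch window
#'   (default 3).
#' @param notch_window Window relative to the upstroke carrying the
#'   notch weight (ms, default 5 to 50).
#' @param cv_weight Weight applied to each CV residual, in residual
#'   units per cm/s (default 0.02, so a 5 cm/s miss costs as much as a
#'   0.1 voltage miss).
#' @param units `"auto"` (default), `"dimensionless"` or `"mV"`.
#' @param convention A [voltage_convention()] for mV templates.
#' @return A `fit_problem` object.
#' @export
fit_problem <- function(templates, cv_targets = NULL, notch_weight = 3,
                        notch_window = c(5, 50), cv_weight = 0.02,
                        units = c("auto", "dimensionless", "mV"),
                        convention = voltage_convention()) {
  units <- match.arg(units)
  if (inherits(templates, "data.frame") || !is.null(templates$time))
    templates <- list(templates)
  stopifnot(length(templates) >= 1, notch_weight > 0, cv_weight >= 0)
  templates <- lapply(templates, function(tp) {
    tp <- as.list(tp)
    stopifnot(!is.null(tp$bcl), !is.null(tp$time), !is.null(tp$V))
    v <- as.numeric(tp$V)
    is_mV <- switch(units, mV = TRUE, dimensionless = FALSE,
                    auto = diff(range(v)) > 5)
    if (is_mV) v <- from_millivolts(v, convention)
    list(bcl = tp$bcl, time = as.numeric(tp$time), V = v)
  })
  structure(list(templates = templates, cv_targets = cv_targets,
                 notch_weight = notch_weight,
                 notch_window = notch_window, cv_weight = cv_weight),
            class = "fit_problem")
}

# upstroke time: first upward crossing of V = 0.5 (linear interpolation)
upstroke_time <- function(time, V, level = 0.5) {
  i <- which(V[-length(V)] < level & V[-1] >= level)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  time[i] + (level - V[i]) / (V[i + 1] - V[i]) * (time[i + 1] - time[i])
}

#' Weighted residual vector of a parameter set against a fit problem
#'
#' For each template the cell is paced at the template's cycle length
#' for `pre_beats` beats; the final-beat voltage is aligned to the
#' template at the upstroke (V = 0.5 crossing) and sampled at the
#' template's time points. Residuals are `weight * (model - template)`,
#' concatenated over templates, followed by scaled CV residuals from
#' short-cable runs when CV targets are present. A simulation that
#' blows up or never excites yields large finite penalty residuals, so
#' optimizers survive bad corners of parameter space.
#'
#' @param params An [ap_params()] set.
#' @param problem A [fit_problem()].
#' @param dt Integration step (ms).
#' @param pre_beats Pacing beats before the measured beat (default 10).
#' @param stim_amplitude Stimulus amplitude, or `NULL` to use 1.5x the
#'   threshold of `params` (recomputed per call).
#' @return Numeric residual vector with attribute `lengths` (per-block
#'   sizes).
#' @export
ap_objective <- function(params, problem, dt = 0.01, pre_beats = 10,
                         stim_amplitude = NULL) {
  stopifnot(inherits(problem, "fit_problem"))
  penalty <- function(n) rep(10, n)
  amp <- stim_amplitude %||% tryCatch(
    1.5 * find_stimulus_threshold(params, dt), error = function(e) NULL)
  blocks <- lapply(problem$templates, function(tp) {
    if (is.null(amp)) return(penalty(length(tp$time)))
    tr <- tryCatch(
      simulate_cell(params,
                    cell_pacing(amp, bcl = tp$bcl, n_beats = pre_beats),
                    duration = tp$bcl * pre_beats, dt = dt,
                    record_dt = min(1, diff(tp$time[1:2]))),
      error = function(e) NULL)
    if (is.null(tr)) return(penalty(length(tp$time)))
    # final beat, aligned at the upstroke
    t_start <- tp$bcl * (pre_beats - 1)
    sel <- tr$time >= t_start - 5
    t_mod <- upstroke_time(tr$time[sel], tr$V[sel])
    t_tpl <- upstroke_time(tp$time, tp$V)
    if (is.na(t_mod) || is.na(t_tpl)) return(penalty(length(tp$time)))
    vm <- approx(tr$time, tr$V, xout = tp$time - t_tpl + t_mod,
                 rule = 2)$y
    w <- rep(1, length(tp$time))
    in_notch <- tp$time >= t_tpl + problem$notch_window[1] &
      tp$time <= t_tpl + problem$notch_window[2]
    w[in_notch] <- problem$notch_weight
    w * (vm - tp$V)
  })
  if (!is.null(problem$cv_targets) && nrow(problem$cv_targets)) {
    cvres <- vapply(seq_len(nrow(problem$cv_targets)), function(k) {
      tgt <- problem$cv_targets[k, ]
      cv <- tryCatch(
        cv_restitution(params, tgt$bcl, cable_length = 3,
                       probes = c(1, 2), beats = 3, dt = dt,
                       amplitude = amp)$cv[1],
        error = function(e) NA_real_)
      if (!is.finite(cv)) 10 else problem$cv_weight * (cv - tgt$cv)
    }, 0)
    blocks <- c(blocks, list(cvres))
  }
  res <- unlist(blocks, use.names = FALSE)
  attr(res, "lengths") <- vapply(blocks, length, 0L)
  res
}

#' Fit model parameters to AP templates
#'
#' Bounded Levenberg-Marquardt least squares over a chosen free subset
#' of the parameters (by default the conductances and gate time
#' constants, which enter the dynamics smoothly; the switching
#' thresholds make the objective discontinuous and are better held
#' fixed). Free parameters are optimized on a log scale, which keeps
#' them positive and makes the bounds multiplicative. Optionally
#' restarts from jittered initial points; with a fixed `seed` the whole
#' procedure is deterministic.
#'
#' @param problem A [fit_problem()].
#' @param start An [ap_params()] initial guess.
#' @param free Character vector of free parameter names (default: the
#'   four conductances and eight time constants). May be empty, in
#'   which case the start is returned with its cost.
#' @param lower,upper Named bounds on free parameters; defaults are
#'   start/8 and start*8.
#' @param dt,pre_beats Passed to [ap_objective()].
#' @param stim_amplitude Fixed stimulus amplitude for all objective
#'   evaluations; default 1.5x the threshold of `start`.
#' @param n_starts Number of optimization starts (default 1); starts
#'   beyond the first jitter the free parameters by up to +/-20%.
#' @param seed Integer seed for the jitter (ignored when
#'   `n_starts = 1`).
#' @param control Passed to [minpack.lm::nls.lm.control()]. The
#'   default forward-difference step (`epsfcn = 1e-4`, i.e. 1% steps)
#'   bridges the staircase microstructure that the step-function
#'   kinetics impose on the discrete trajectory; much smaller steps see
#'   a locally flat objective.
#' @return An `ap_fit` object: `params` (fitted set), `cost` (sum of
#'   squared residuals), `rms` (per-template voltage RMS),
#'   `convergence` (optimizer message/status), `starts` (per-start
#'   summary), `start`, `free`.
#' @export
fit_ap_model <- function(problem, start, free = NULL, lower = NULL,
                         upper = NULL, dt = 0.01, pre_beats = 10,
                         stim_amplitude = NULL, n_starts = 1,
                         seed = NULL,
                         control = list(maxiter = 50, epsfcn = 1e-4)) {
  stopifnot(inherits(problem, "fit_problem"), inherits(start, "ap_params"))
  free <- free %||% c("g_fi", "g_so", "g_si", "g_to",
                      "tau_h_plus", "tau_h_minus", "tau_f_plus",
                      "tau_f_minus", "tau_r_plus", "tau_r_minus",
                      "tau_s_plus", "tau_s_minus")
  bad <- setdiff(free, names(unclass(start)))
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "))
  x0 <- if (length(free)) log(unlist(unclass(start)[free])) else numeric(0)
  # optimize the log-ratio to the start (all components start at 0, so
  # the finite-difference step of the numerical Jacobian is uniform)
  build <- function(dlog) {
    vals <- as.list(exp(x0 + dlog))
    names(vals) <- free
    do.call(modify_params, c(list(start), vals))
  }
  # the stimulus amplitude is frozen at 1.5x the threshold of the
  # starting set: recomputing the bisection threshold at every
  # objective call would make the cost surface non-smooth
  amp <- stim_amplitude %||% (1.5 * find_stimulus_threshold(start, dt))
  resid_fun <- function(dlog) {
    p <- tryCatch(build(dlog), error = function(e) NULL)
    if (is.null(p)) return(rep(10, .nres))
    as.numeric(ap_objective(p, problem, dt, pre_beats, amp))
  }
  .nres <- length(ap_objective(start, problem, dt, pre_beats, amp))

  if (length(free) == 0) {
    cost <- sum(ap_objective(start, problem, dt, pre_beats,
                             stim_amplitude)^2)
    return(structure(list(params = start, cost = cost, rms = NA,
                          convergence = "no free parameters",
                          starts = NULL, start = start, free = free),
                     class = "ap_fit"))
  }
  lov <- exp(x0) / 8; hiv <- exp(x0) * 8
  if (!is.null(lower)) lov[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hiv[names(upper)] <- unlist(upper)
  lo <- log(lov) - x0; hi <- log(hiv) - x0
  if (any(lo > 0) || any(hi < 0))
    stop("bounds must contain the initial guess")

  jitters <- list(rep(0, length(x0)))  # delta-log starts
  if (n_starts > 1) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    for (k in seq_len(n_starts - 1))
      jitters[[k + 1]] <- log(runif(length(x0), 0.8, 1.2))
  }
  ctrl <- do.call(minpack.lm::nls.lm.control, control)
  starts <- lapply(jitters, function(j) {
    xj <- pmin(pmax(j, lo), hi)
    # non-convergence is reported through the diagnostics, not raised
    fit <- suppressWarnings(
      minpack.lm::nls.lm(par = xj, lower = lo, upper = hi,
                         fn = resid_fun, control = ctrl))
    list(par = fit$par, cost = sum(fit$fvec^2), info = fit$info,
         message = fit$message, niter = fit$niter)
  })
  best <- starts[[which.min(vapply(starts, `[[`, 0, "cost"))]]
  params <- build(best$par)
  res <- ap_objective(params, problem, dt, pre_beats, amp)
  lens <- attr(res, "lengths")
  ntpl <- length(problem$templates)
  idx <- split(seq_along(res), rep(seq_along(lens), lens))
  rms <- vapply(idx[seq_len(ntpl)],
                function(i) sqrt(mean(res[i]^2)), 0)
  structure(list(params = params, cost = best$cost, rms = rms,
                 convergence = paste0("nls.lm info ", best$info, ": ",
                                      best$message),
                 starts = starts, start = start, free = free),
            class = "ap_fit")
}

#' @export
coef.ap_fit <- function(object, ...) {
  unlist(unclass(object$params)[object$free])
}

#' @export
print.ap_fit <- function(x, ...) {
  cat("ap_fit: ", length(x$free), " free parameter(s), cost = ",
      format(x$cost, digits = 5), "\n", sep = "")
  if (length(x$free)) print(coef(x))
  cat(x$convergence, "\n")
  invisible(x)
}

#' @export
summary.ap_fit <- function(object, ...) {
  cat("Fit of the four-current AP model\n")
  print(object)
  if (!all(is.na(object$rms)))
    cat("per-template voltage RMS:",
        format(object$rms, digits = 4), "\n")
  st <- unlist(unclass(object$start)[object$free])
  if (length(object$free)) {
    rel <- coef(object) / st - 1
    cat("relative change from start:\n")
    print(round(rel, 4))
  }
  invisible(object)
}

#' Read an AP template from two-column delimited text
#'
#' Lines starting with `#` are ignored; the first two columns are time
#' (ms) and voltage (mV or dimensionless).
#'
#' @param path File path.
#' @param bcl Pacing period of the template (ms).
#' @return A template list for [fit_problem()].
#' @export
read_template <- function(path, bcl) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#")
  list(bcl = bcl, time = df[[1]], V = df[[2]])
}
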