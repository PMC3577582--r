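#' Stimulation threshold of a single cell
#'
#' Bisection on the amplitude of a 1-ms depolarizing pulse applied to a
#' resting cell. An amplitude excites when the voltage exceeds 0.8
#' within 20 ms of pulse onset. The standard stimulus used throughout
#' the protocols is 1.5 times this threshold.
#'
#' @param params An [ap_params()] set.
#' @param dt Integration step (ms).
#' @param duration Pulse duration (ms, default 1).
#' @param upper Upper bracket amplitude (ms^-1); an error is raised if
#'   it fails to excite.
#' @param tol Relative tolerance of the final bracket (default 1e-3).
#' @return Threshold amplitude (ms^-1), midpoint of the final bracket.
#' @export
find_stimulus_threshold <- function(params, dt = 0.01, duration = 1,
                                    upper = 10, tol = 1e-3) {
  excites <- function(amp) {
    tr <- simulate_cell(params,
                        cell_pacing(amp, n_beats = 1, duration = duration),
                        duration = 20 + duration, dt = dt,
                        record_dt = 0.1)
    max(tr$V) > 0.8
  }
  if (!excites(upper))
    stop("upper bracket amplitude ", upper, " ms^-1 fails to excite")
  lo <- 0; hi <- upper
  while ((hi - lo) > tol * hi) {
    mid <- (lo + hi) / 2
    if (excites(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Threshold-crossing times of a trace
#'
#' Linearly interpolated times at which a voltage trace crosses a level
#' in the given direction. The activation time of a propagating beat is
#' the upward crossing of V = 0.5 (the steep upstroke, insensitive to
#' the exact level).
#'
#' @param trace Data.frame with `time` and a voltage column.
#' @param level Crossing level (dimensionless voltage).
#' @param column Voltage column name (default `"V"` or the first
#'   non-time column).
#' @param direction `"up"` (rising) or `"down"` (falling).
#' @return Numeric vector of crossing times (ms), possibly empty.
#' @export
crossing_times <- function(trace, level = 0.5, column = NULL,
                           direction = c("up", "down")) {
  direction <- match.arg(direction)
  df <- as.data.frame(trace)
  if (is.null(column))
    column <- if ("V" %in% names(df)) "V" else setdiff(names(df), "time")[1]
  t <- df$time; v <- df[[column]]
  if (any(!is.finite(v))) stop("non-finite voltage in trace")
  n <- length(v)
  above <- v >= level
  i <- if (direction == "up") which(!above[-n] & above[-1])
       else which(above[-n] & !above[-1])
  vapply(i, function(k)
    t[k] + (level - v[k]) / (v[k + 1] - v[k]) * (t[k + 1] - t[k]), 0)
}

#' Measure APD and DI from a voltage trace
#'
#' Per beat, the action potential duration is the time between the
#' upward and downward crossings of the threshold voltage (linear
#' interpolation between samples); the diastolic interval is the time
#' from a downward crossing to the next upward crossing.
#'
#' @param trace An `ap_trace` or any data.frame with `time` and `V`
#'   columns (a probe column may be selected with `column`).
#' @param threshold Threshold voltage (dimensionless, default 0.1,
#'   about -75 mV / 90% repolarization).
#' @param column Name of the voltage column (default `"V"`, or the
#'   first probe column present).
#' @return Data.frame with one row per complete AP: `t_up`, `t_down`,
#'   `apd`, `di` (the DI preceding that AP; `NA` for the first).
#'   Empty for a trace that never crosses the threshold.
#' @export
measure_apd <- function(trace, threshold = 0.1, column = NULL) {
  df <- as.data.frame(trace)
  if (is.null(column))
    column <- if ("V" %in% names(df)) "V" else setdiff(names(df), "time")[1]
  t_up <- crossing_times(df, threshold, column, "up")
  t_dn <- crossing_times(df, threshold, column, "down")
  if (nrow(df) && df[[column]][1] >= threshold) {
    # trace starts above threshold: drop the unmatched leading downstroke
    if (length(t_dn)) t_dn <- t_dn[-1]
  }
  nb <- min(length(t_up), length(t_dn))
  if (nb == 0)
    return(data.frame(t_up = numeric(0), t_down = numeric(0),
                      apd = numeric(0), di = numeric(0)))
  t_up <- t_up[seq_len(nb)]; t_dn <- t_dn[seq_len(nb)]
  data.frame(t_up = t_up, t_down = t_dn, apd = t_dn - t_up,
             di = c(NA, t_up[-1] - t_dn[-nb]))
}

#' Dynamic APD restitution
#'
#' For each basic cycle length, the cell is paced to an approximate
#' steady state (the model has no slow concentration memory, so a
#' handful of pre-beats suffices) and the APD of the final beat is
#' recorded against the preceding diastolic interval. Cycle lengths
#' that lose 1:1 capture (e.g. 2:1 block below refractoriness) are
#' reported as dropped rather than raising.
#'
#' @param params An [ap_params()] set.
#' @param bcl Vector of basic cycle lengths (ms).
#' @param beats Beats per cycle length (default 10).
#' @param dt Integration step (ms).
#' @param threshold APD threshold voltage (default 0.1).
#' @param amplitude Stimulus amplitude; default 1.5x the cell threshold.
#' @return A `restitution_curve` data.frame with columns `bcl`, `di`,
#'   `apd`, `captured`.
#' @export
apd_restitution <- function(params, bcl, beats = 10, dt = 0.01,
                            threshold = 0.1, amplitude = NULL) {
  amplitude <- amplitude %||% (1.5 * find_stimulus_threshold(params, dt))
  rows <- lapply(bcl, function(b) {
    tr <- simulate_cell(params,
                        cell_pacing(amplitude, bcl = b, n_beats = beats),
                        duration = b * beats, dt = dt, record_dt = 0.5)
    ap <- measure_apd(tr, threshold)
    ok <- nrow(ap) == beats && !is.na(ap$di[beats])
    data.frame(bcl = b,
               di = if (ok) ap$di[beats] else NA_real_,
               apd = if (ok) ap$apd[beats] else NA_real_,
               captured = ok)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("restitution_curve", "data.frame"),
            kind = "apd", params_label = params$label,
            beats = beats, threshold = threshold)
}

#' Conduction-velocity restitution in a 1D cable
#'
#' Paces one end of a cable and measures the planar conduction velocity
#' between two interior probes (upstroke crossing of V = 0.5, linearly
#' interpolated) for the final beat at each cycle length.
#'
#' @inheritParams apd_restitution
#' @param D Scalar diffusion coefficient (cm^2/ms, default 1e-3).
#' @param dx Node spacing (cm, default 0.02).
#' @param cable_length Cable length (cm, default 8).
#' @param probes Two probe positions (cm, default 3 and 5).
#' @param beats Beats per cycle length (default 5).
#' @param stim_width Width of the stimulated end segment (cm).
#' @param activation_V Upstroke detection level (default 0.5).
#' @return A `restitution_curve` data.frame with columns `bcl`, `di`,
#'   `cv` (cm/s), `captured`.
#' @export
cv_restitution <- function(params, bcl, D = 1e-3, dx = 0.02, dt = 0.01,
                           cable_length = 8, probes = c(3, 5), beats = 5,
                           amplitude = NULL, stim_width = 0.2,
                           threshold = 0.1, activation_V = 0.5) {
  stopifnot(length(probes) == 2, probes[1] < probes[2])
  if (min(probes) < 1 || max(probes) > cable_length - 1)
    stop("probes must sit at least 1 cm from both cable ends")
  amplitude <- amplitude %||% (1.5 * find_stimulus_threshold(params, dt))
  grid <- cable_grid(cable_length, dx, D)
  rows <- lapply(bcl, function(b) {
    ev <- stim_event(list(x = c(0, stim_width)), start = 0, duration = 1,
                     amplitude = amplitude, bcl = b, n_beats = beats)
    run <- simulate_tissue(grid, params, ev, duration = b * beats,
                           dt = dt, probes = probes, record_dt = 0.1)
    a1 <- crossing_times(run$probes, activation_V, "p1")
    a2 <- crossing_times(run$probes, activation_V, "p2")
    if (length(a2) == 0)
      stop("wave failed to reach the distal probe at BCL = ", b)
    ok <- length(a1) == beats && length(a2) == beats
    cv <- if (ok)
      (probes[2] - probes[1]) / (a2[beats] - a1[beats]) * 1000
    else NA_real_
    ups <- crossing_times(run$probes, threshold, "p2", "up")
    dns <- crossing_times(run$probes, threshold, "p2", "down")
    di <- if (ok && length(ups) == beats && length(dns) >= beats - 1)
      ups[beats] - dns[beats - 1] else NA_real_
    data.frame(bcl = b, di = di, cv = cv, captured = ok)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("restitution_curve", "data.frame"),
            kind = "cv", params_label = params$label, beats = beats,
            D = D, dx = dx, probes = probes)
}

#' @export
print.restitution_curve <- function(x, ...) {
  cat(toupper(attr(x, "kind")), " restitution [",
      attr(x, "params_label"), "], ", sum(x$captured), "/", nrow(x),
      " cycle lengths captured\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
plot.restitution_curve <- function(x, ...) {
  ycol <- if (attr(x, "kind") == "cv") "cv" else "apd"
  ok <- x$captured & is.finite(x$di)
  plot(x$di[ok], x[[ycol]][ok], type = "b", xlab = "DI (ms)",
       ylab = if (ycol == "cv") "CV (cm/s)" else "APD (ms)", ...)
  invisible(x)
}

#' Export a restitution curve as delimited text
#' @param curve A `restitution_curve`.
#' @param path Output file.
#' @export
write_restitution <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fourcurrent %s restitution; params=%s; beats=%s",
                     attr(curve, "kind"),
                     attr(curve, "params_label") %||% "NA",
                     attr(curve, "beats") %||% "NA"), con)
  utils::write.table(as.data.frame(curve), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
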