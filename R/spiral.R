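#' Initiate a spiral wave by S1-S2 cross-field stimulation
#'
#' An S1 plane wave is launched from the left edge of a square sheet;
#' when the mid-domain node recrosses the APD threshold on its way down
#' (the repolarization wake), an S2 stimulus is delivered over the
#' lower-left quadrant. The broken S2 wavefront curls around the
#' refractory region and forms a single spiral.
#'
#' @param params An [ap_params()] set.
#' @param grid A 2D [sheet_grid()]; default 10 x 10 cm at dx = 0.02 cm.
#' @param dt Time step (ms).
#' @param amplitude Stimulus amplitude; default 1.5x the cell
#'   threshold.
#' @param threshold APD threshold used to time S2 (default 0.1).
#' @param s2_delay Extra delay (ms) after the wake crossing before S2.
#' @param settle Time (ms) simulated after S2 before the singularity
#'   check.
#' @param check If `TRUE` (default), verify that at least one phase
#'   singularity is present `settle` ms after S2 and raise otherwise.
#' @return List of class `spiral_init`: `state` (field state at `t`),
#'   `t` (ms), `s2_time`, `grid`, `amplitude`.
#' @export
initiate_spiral <- function(params, grid = sheet_grid(10, 10), dt = 0.01,
                            amplitude = NULL, threshold = 0.1,
                            s2_delay = 0, settle = 100, check = TRUE) {
  stopifnot(grid$ndim == 2)
  amplitude <- amplitude %||% (1.5 * find_stimulus_threshold(params, dt))
  Lx <- (grid$dims[1] - 1) * grid$dx
  Ly <- (grid$dims[2] - 1) * grid$dx
  mid <- matrix(c(Lx / 2, Ly / 2), 1)

  s1 <- stim_event(list(x = c(0, 0.1)), start = 0, duration = 1,
                   amplitude = amplitude)
  state <- NULL; t <- 0; was_up <- FALSE; s2_time <- NA
  # chunked integration: coarse before the wake reaches mid-domain,
  # fine while waiting for the downward recrossing
  repeat {
    chunk <- if (was_up) 2 else 10
    run <- simulate_tissue(grid, params, if (t == 0) s1, duration = chunk,
                           dt = dt, init = state, probes = mid,
                           record_dt = min(chunk, 1), t0 = t)
    state <- run$state; t <- run$t_end
    vmid <- run$probes$p1[nrow(run$probes)]
    if (!was_up && vmid >= threshold) was_up <- TRUE
    if (was_up && vmid < threshold) { s2_time <- t; break }
    if (t > 2000) stop("S1 wake never crossed mid-domain; no S2 applied")
  }
  s2_time <- s2_time + s2_delay
  s2 <- stim_event(list(x = c(0, Lx / 2), y = c(0, Ly / 2)),
                   start = s2_time, duration = 1, amplitude = amplitude)
  run <- simulate_tissue(grid, params, s2, duration = s2_delay + settle,
                         dt = dt, init = state, probes = mid,
                         record_dt = 1, t0 = t,
                         snapshot_dt = 2,
                         snapshot_window = c(s2_time + settle - 10,
                                             s2_time + settle))
  if (check) {
    tips <- track_spiral_tip(run$frames, run$frame_t, grid)
    if (nrow(tips) == 0)
      stop("no phase singularity ", settle, " ms after S2; ",
           "try shifting S2 with `s2_delay` (e.g. +10 or -10 ms)")
  }
  structure(list(state = run$state, t = run$t_end, s2_time = s2_time,
                 grid = grid, amplitude = amplitude,
                 params_label = params$label),
            class = "spiral_init")
}

# all transversal intersections of the V = V_iso and dV/dt = 0 contours
# inside one frame pair, by per-cell bilinear root finding
tips_in_frame <- function(A, B, dx) {
  nx <- nrow(A); ny <- ncol(A)
  sA <- A >= 0; sB <- B >= 0
  # cells whose four corners straddle zero in both fields
  cA <- sA[-nx, -ny] | sA[-1, -ny] | sA[-nx, -1] | sA[-1, -1]
  cAn <- (!sA[-nx, -ny]) | (!sA[-1, -ny]) | (!sA[-nx, -1]) | (!sA[-1, -1])
  cB <- sB[-nx, -ny] | sB[-1, -ny] | sB[-nx, -1] | sB[-1, -1]
  cBn <- (!sB[-nx, -ny]) | (!sB[-1, -ny]) | (!sB[-nx, -1]) | (!sB[-1, -1])
  cand <- which(cA & cAn & cB & cBn, arr.ind = TRUE)
  if (nrow(cand) == 0) return(matrix(numeric(0), 0, 2))
  out <- matrix(NA_real_, nrow(cand), 2)
  nout <- 0
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    a00 <- A[i, j]; a10 <- A[i + 1, j]; a01 <- A[i, j + 1]; a11 <- A[i + 1, j + 1]
    b00 <- B[i, j]; b10 <- B[i + 1, j]; b01 <- B[i, j + 1]; b11 <- B[i + 1, j + 1]
    al <- c(a00, a10 - a00, a01 - a00, a11 - a10 - a01 + a00)
    be <- c(b00, b10 - b00, b01 - b00, b11 - b10 - b01 + b00)
    # A = al1 + al2 s + al3 u + al4 s u = 0, same for B; eliminate u
    qa <- be[2] * al[4] - be[4] * al[2]
    qb <- be[1] * al[4] + be[2] * al[3] - be[3] * al[2] - be[4] * al[1]
    qc <- be[1] * al[3] - be[3] * al[1]
    roots <- if (abs(qa) < 1e-300) {
      if (abs(qb) < 1e-300) numeric(0) else -qc / qb
    } else {
      disc <- qb^2 - 4 * qa * qc
      if (disc < 0) numeric(0)
      else (-qb + c(1, -1) * sqrt(disc)) / (2 * qa)
    }
    for (s in roots) {
      if (!is.finite(s) || s < 0 || s > 1) next
      den <- al[3] + al[4] * s
      u <- if (abs(den) > 1e-300) -(al[1] + al[2] * s) / den else NA_real_
      if (!is.finite(u) || u < 0 || u > 1) next
      nout <- nout + 1
      out[nout, ] <- c((i - 1 + s) * dx, (j - 1 + u) * dx)
      break
    }
  }
  out[seq_len(nout), , drop = FALSE]
}

#' Track spiral-wave tips
#'
#' The wave tip is the point where the excitation wavefront meets the
#' repolarization waveback: the intersection of the contour `V = V_iso`
#' with the contour `dV/dt = 0`. Per frame pair the time derivative is
#' a forward difference; intersections are located to sub-cell accuracy
#' by bilinear interpolation within each grid cell, and linked over
#' time by nearest neighbor within a gate distance.
#'
#' @param frames Node x frame matrix of voltage snapshots (from
#'   [simulate_tissue()] with `snapshot_dt`).
#' @param times Frame times (ms).
#' @param grid The 2D [tissue_grid] the frames live on.
#' @param V_iso Isopotential level; default half the maximum voltage
#'   observed in the frames.
#' @param gate Maximum per-frame tip displacement for linking (cm).
#' @return A `tip_trajectory` data.frame `(t, x, y)` of the linked tip;
#'   all per-frame intersection points are in `attr(, "all_tips")`.
#'   Zero rows when no tips exist.
#' @export
track_spiral_tip <- function(frames, times, grid, V_iso = NULL,
                             gate = 0.5) {
  stopifnot(grid$ndim == 2, length(times) >= 2)
  nx <- grid$dims[1]; ny <- grid$dims[2]
  V_iso <- V_iso %||% (0.5 * max(frames))
  all_tips <- vector("list", length(times) - 1)
  for (k in seq_len(length(times) - 1)) {
    A <- matrix(frames[, k + 1] - V_iso, nx, ny)
    B <- matrix((frames[, k + 1] - frames[, k]) /
                  (times[k + 1] - times[k]), nx, ny)
    all_tips[[k]] <- tips_in_frame(A, B, grid$dx)
  }
  t_mid <- times[-1]
  # greedy nearest-neighbor linking from the first frame with a tip
  traj <- NULL; cur <- NULL
  for (k in seq_along(all_tips)) {
    tp <- all_tips[[k]]
    if (nrow(tp) == 0) next
    if (is.null(cur)) {
      cur <- tp[1, ]
    } else {
      d <- sqrt((tp[, 1] - cur[1])^2 + (tp[, 2] - cur[2])^2)
      if (min(d) > gate) next
      cur <- tp[which.min(d), ]
    }
    traj <- rbind(traj, c(t_mid[k], cur))
  }
  if (is.null(traj))
    traj <- matrix(numeric(0), 0, 3)
  out <- data.frame(t = traj[, 1], x = traj[, 2], y = traj[, 3])
  structure(out, class = c("tip_trajectory", "data.frame"),
            all_tips = all_tips, V_iso = V_iso, times = t_mid)
}

#' Spiral period statistics from a probe trace
#'
#' The rotation period is the mean interval between successive
#' activations (upward crossings of the threshold) at a fixed probe;
#' APD and DI per rotation come from [measure_apd()]. The identity
#' `T = APD + DI` is checked per rotation.
#'
#' @param trace Probe data.frame (`time` plus a voltage column).
#' @param threshold APD threshold (default 0.1).
#' @param discard Initial transient to drop (ms, default 500).
#' @param min_rotations Minimum complete rotations required (default 5).
#' @param column Voltage column (defaults as in [measure_apd()]).
#' @return List of class `spiral_stats`: `T`, `APD`, `DI` (ms, means),
#'   `n_rotations`, and the per-rotation table in `$rotations`.
#' @export
spiral_statistics <- function(trace, threshold = 0.1, discard = 500,
                              min_rotations = 5, column = NULL) {
  df <- as.data.frame(trace)
  df <- df[df$time >= discard, , drop = FALSE]
  ap <- measure_apd(df, threshold, column = column)
  if (nrow(ap) < min_rotations + 1)
    stop("fewer than ", min_rotations, " complete rotations after the ",
         discard, " ms discard window")
  periods <- diff(ap$t_up)
  nb <- nrow(ap)
  # rotation j runs from activation j to activation j+1: its APD is that
  # of beat j and its DI the recovery gap before beat j+1, so
  # T_j = APD_j + DI_{j+1} holds exactly by construction
  rot <- data.frame(t_up = ap$t_up[-nb], T = periods,
                    apd = ap$apd[-nb], di = ap$di[-1])
  structure(list(T = mean(periods), APD = mean(rot$apd),
                 DI = mean(rot$di), n_rotations = length(periods),
                 rotations = rot),
            class = "spiral_stats")
}

#' @export
print.spiral_stats <- function(x, ...) {
  cat(sprintf("spiral: T = %.1f ms (APD = %.1f ms, DI = %.1f ms), %d rotations\n",
              x$T, x$APD, x$DI, x$n_rotations))
  invisible(x)
}

#' Full spiral-wave experiment
#'
#' Initiates a spiral by S1-S2 cross-field stimulation, lets it rotate,
#' tracks the tip over a snapshot window, and measures the rotation
#' period, APD and DI at a probe chosen at least `probe_min_dist` cm
#' from the tip-trajectory centroid.
#'
#' @inheritParams initiate_spiral
#' @param L Sheet side (cm, default 6; the published domain is 10).
#' @param dx Node spacing (cm).
#' @param D Diffusion coefficient (cm^2/ms).
#' @param duration Rotation time simulated after S2 (ms).
#' @param discard Transient dropped before statistics (ms, counted from
#'   S2).
#' @param tip_window Length of the tip-tracking window (ms) at the end
#'   of the discard period.
#' @param snapshot_dt Frame cadence for tip tracking (ms).
#' @param probe_min_dist Minimum probe distance from the tip centroid
#'   (cm).
#' @return List of class `spiral_run`: `stats` (a
#'   [spiral_statistics()] result), `tips` (a tip trajectory), `probe`
#'   (cm), `probes` (all candidate traces), `init`.
#' @export
spiral_experiment <- function(params, L = 6, dx = 0.02, D = 1e-3,
                              dt = 0.01, duration = 3900, discard = 700,
                              tip_window = 300, snapshot_dt = 2,
                              amplitude = NULL, threshold = 0.1,
                              s2_delay = 0, probe_min_dist = 2) {
  grid <- sheet_grid(L, L, dx, D)
  init <- initiate_spiral(params, grid, dt, amplitude = amplitude,
                          threshold = threshold, s2_delay = s2_delay)
  # candidate probes: ring of points away from the domain center
  frac <- rbind(c(.12, .12), c(.12, .88), c(.88, .12), c(.88, .88),
                c(.5, .9), c(.9, .5), c(.1, .5), c(.5, .1))
  probes <- frac * L
  t1 <- init$t + discard
  run <- simulate_tissue(grid, params, NULL, duration = duration,
                         dt = dt, init = init$state, probes = probes,
                         record_dt = 1, t0 = init$t,
                         snapshot_dt = snapshot_dt,
                         snapshot_window = c(t1 - tip_window, t1))
  tips <- track_spiral_tip(run$frames, run$frame_t, grid)
  if (nrow(tips) == 0)
    stop("spiral terminated before the measurement window")
  ctr <- c(mean(tips$x), mean(tips$y))
  dist <- sqrt((probes[, 1] - ctr[1])^2 + (probes[, 2] - ctr[2])^2)
  stats <- NULL; chosen <- NA
  for (q in order(dist, decreasing = TRUE)) {
    if (dist[q] < probe_min_dist) break
    st <- tryCatch(
      spiral_statistics(run$probes, threshold,
                        discard = init$t + discard,
                        column = paste0("p", q)),
      error = function(e) NULL)
    if (!is.null(st)) { stats <- st; chosen <- q; break }
  }
  if (is.null(stats))
    stop("no probe at least ", probe_min_dist,
         " cm from the core recorded 5 clean rotations")
  structure(list(stats = stats, tips = tips, probe = probes[chosen, ],
                 probe_dist = dist[chosen], probes = run$probes,
                 init = init, grid = grid),
            class = "spiral_run")
}

#' @export
print.spiral_run <- function(x, ...) {
  print(x$stats)
  cat(sprintf("probe at (%.1f, %.1f) cm, %.1f cm from tip centroid; tip tracked over %d frames\n",
              x$probe[1], x$probe[2], x$probe_dist, nrow(x$tips)))
  invisible(x)
}
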