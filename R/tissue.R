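#' Tissue grids for the monodomain solver
#'
#' Uniform node-centered grids (physical coordinate of node `i` along an
#' axis is `(i-1)*dx` cm) with zero-flux boundaries. Diffusion is either
#' a scalar `D` (cm^2/ms) or, for voxel geometries, a per-node
#' transversely isotropic tensor built from a fiber unit vector and the
#' longitudinal/transverse diffusivities.
#'
#' @param length_cm Cable length (cm).
#' @param dx Node spacing (cm; reference values 0.02 for 1D/2D, 0.025
#'   for 3D).
#' @param D Scalar diffusion coefficient (cm^2/ms).
#' @return A `tissue_grid` object.
#' @name tissue_grid
NULL

new_tissue_grid <- function(ndim, dims, dx, D = NULL, mask = NULL,
                            fibers = NULL, D_par = NULL, D_perp = NULL) {
  stopifnot(dx > 0, all(dims >= 1))
  structure(list(ndim = ndim, dims = as.integer(dims), dx = dx, D = D,
                 mask = mask, fibers = fibers, D_par = D_par,
                 D_perp = D_perp),
            class = "tissue_grid")
}

#' @rdname tissue_grid
#' @export
cable_grid <- function(length_cm = 8, dx = 0.02, D = 1e-3) {
  nx <- round(length_cm / dx) + 1L
  new_tissue_grid(1L, c(nx, 1L), dx, D = D)
}

#' @rdname tissue_grid
#' @param Lx,Ly Sheet side lengths (cm).
#' @export
sheet_grid <- function(Lx = 10, Ly = Lx, dx = 0.02, D = 1e-3) {
  new_tissue_grid(2L, c(round(Lx / dx) + 1L, round(Ly / dx) + 1L), dx,
                  D = D)
}

#' @rdname tissue_grid
#' @param mask 3D logical/0-1 array marking in-tissue voxels.
#' @param fibers Array `c(dim(mask), 3)` of fiber unit vectors, or
#'   `NULL` for isotropic diffusion.
#' @param D_par,D_perp Diffusivities along and across the fiber
#'   (cm^2/ms); reference values 1e-3 and 6.75e-5.
#' @export
voxel_grid <- function(mask, dx = 0.025, fibers = NULL, D = NULL,
                       D_par = 1e-3, D_perp = 6.75e-5) {
  mask <- array(as.integer(mask != 0), dim = dim(mask))
  if (sum(mask) == 0) stop("tissue mask is empty")
  if (is.null(fibers) && is.null(D)) D <- D_par
  new_tissue_grid(length(dim(mask)), dim(mask), dx, D = D, mask = mask,
                  fibers = fibers, D_par = D_par, D_perp = D_perp)
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat("tissue_grid: ", x$ndim, "D, ", paste(x$dims, collapse = " x "),
      " nodes, dx = ", x$dx, " cm\n", sep = "")
  if (!is.null(x$mask))
    cat("masked: ", sum(x$mask), " in-tissue voxels\n", sep = "")
  cat(if (is.null(x$fibers)) paste0("scalar D = ", x$D)
      else paste0("anisotropic: D_par = ", x$D_par,
                  ", D_perp = ", x$D_perp), "cm^2/ms\n")
  invisible(x)
}

n_nodes <- function(grid) prod(grid$dims)

grid_mask_vec <- function(grid) {
  if (is.null(grid$mask)) rep(1L, n_nodes(grid))
  else as.integer(grid$mask)
}

# per-node 6-column tensor (xx, yy, zz, xy, xz, yz)
grid_tensor <- function(grid) {
  n <- n_nodes(grid)
  if (is.null(grid$fibers)) {
    tens <- matrix(0, n, 6)
    tens[, 1:3] <- grid$D
    return(tens)
  }
  f <- matrix(grid$fibers, ncol = 3)
  nrm <- sqrt(rowSums(f^2))
  nrm[nrm == 0] <- 1
  f <- f / nrm
  dd <- grid$D_par - grid$D_perp
  cbind(grid$D_perp + dd * f[, 1]^2,
        grid$D_perp + dd * f[, 2]^2,
        grid$D_perp + dd * f[, 3]^2,
        dd * f[, 1] * f[, 2],
        dd * f[, 1] * f[, 3],
        dd * f[, 2] * f[, 3])
}

grid_dmax <- function(grid) {
  if (is.null(grid$fibers)) grid$D else max(grid$D_par, grid$D_perp)
}

#' Largest stable explicit time step
#'
#' Explicit-Euler diffusion stability bound `dx^2 / (2 ndim Dmax)`.
#'
#' @param grid A [tissue_grid].
#' @return Bound in ms.
#' @export
stability_limit <- function(grid) {
  grid$dx^2 / (2 * grid$ndim * grid_dmax(grid))
}

#' Conservative diffusion operator
#'
#' Flux-form finite-difference divergence of `D grad V` with zero-flux
#' boundaries at the domain edge and at mask boundaries. Every interior
#' face carries a single flux added to one node and subtracted from its
#' neighbor, so the sum over nodes vanishes to round-off. For scalar D
#' on a full grid this reduces to `D/dx^2` times the standard
#' 3/5/7-point Laplacian.
#'
#' @param V Field (vector or array matching the grid dims).
#' @param grid A [tissue_grid].
#' @return Array of `div(D grad V)` values (ms^-1), zero outside the
#'   mask.
#' @export
diffusion_term <- function(V, grid) {
  v <- as.numeric(V)
  stopifnot(length(v) == n_nodes(grid))
  out <- diffusion_term_cpp(v, grid$dims, grid$dx, grid_mask_vec(grid),
                            grid_tensor(grid))
  if (grid$ndim > 1) array(out, dim = grid$dims) else out
}

#' Stimulus events for tissue runs
#'
#' A stimulus event injects a depolarizing current of the given
#' amplitude into a region for a fixed duration, optionally repeated at
#' a basic cycle length.
#'
#' @param region Either a list of physical coordinate ranges in cm
#'   (`list(x = c(0, 0.2))`, `y =`, `z =`; omitted axes cover
#'   everything), or a vector of 1-based flat node indices.
#' @param start Onset time (ms).
#' @param duration Pulse length (ms, default 1).
#' @param amplitude Current (ms^-1).
#' @param bcl,n_beats Repetition: period (ms) and number of pulses.
#' @return Object of class `stim_event`.
#' @export
stim_event <- function(region, start = 0, duration = 1, amplitude,
                       bcl = NULL, n_beats = 1) {
  stopifnot(duration > 0, n_beats >= 1)
  if (n_beats > 1 && (is.null(bcl) || bcl <= duration))
    stop("BCL must exceed the stimulus duration when repeating")
  structure(list(region = region, start = start, duration = duration,
                 amplitude = amplitude, bcl = bcl, n_beats = n_beats),
            class = "stim_event")
}

#' @rdname stim_event
#' @param ... `stim_event` objects.
#' @export
stim_protocol <- function(...) {
  evs <- list(...)
  if (length(evs) == 1 && is.list(evs[[1]]) &&
      !inherits(evs[[1]], "stim_event")) evs <- evs[[1]]
  stopifnot(all(vapply(evs, inherits, TRUE, "stim_event")))
  structure(evs, class = "tissue_protocol")
}

# resolve a region spec to 0-based flat node indices
region_index <- function(region, grid) {
  if (is.numeric(region)) {
    idx <- as.integer(region) - 1L
  } else {
    dims <- grid$dims
    ax <- c("x", "y", "z")
    keep <- rep(TRUE, n_nodes(grid))
    coords <- arrayInd(seq_len(n_nodes(grid)),
                       c(dims, rep(1L, 3 - length(dims)))[1:3])
    for (a in 1:3) {
      rng <- region[[ax[a]]]
      if (!is.null(rng)) {
        pos <- (coords[, a] - 1) * grid$dx
        keep <- keep & pos >= rng[1] & pos <= rng[2]
      }
    }
    idx <- which(keep) - 1L
  }
  if (!is.null(grid$mask)) idx <- idx[grid_mask_vec(grid)[idx + 1L] == 1L]
  if (length(idx) == 0) stop("stimulus region contains no tissue nodes")
  idx
}

# expand protocol into the flat per-pulse event list used by the kernels
expand_events <- function(protocol, grid) {
  if (is.null(protocol)) return(list())
  if (inherits(protocol, "stim_event")) protocol <- stim_protocol(protocol)
  out <- list()
  for (ev in protocol) {
    idx <- region_index(ev$region, grid)
    for (b in seq_len(ev$n_beats)) {
      on <- ev$start + (b - 1) * (ev$bcl %||% 0)
      out[[length(out) + 1L]] <- list(idx = idx, t_on = on,
                                      t_off = on + ev$duration,
                                      amplitude = ev$amplitude)
    }
  }
  out
}

#' All-resting field state for a grid
#' @param grid A [tissue_grid].
#' @return List of per-node state vectors (V, h, f, r, s) at the
#'   analytic resting state.
#' @export
resting_field <- function(grid) {
  n <- n_nodes(grid)
  rest <- resting_state()
  list(V = rep(rest[["V"]], n), h = rep(rest[["h"]], n),
       f = rep(rest[["f"]], n), r = rep(rest[["r"]], n),
       s = rep(rest[["s"]], n))
}

# nearest node (0-based flat index) to physical coordinates (cm)
probe_index <- function(probes, grid) {
  if (is.null(probes)) return(integer(0))
  if (is.numeric(probes) && is.null(dim(probes)) && grid$ndim == 1)
    probes <- matrix(probes, ncol = 1)
  pm <- as.matrix(probes)
  dims <- grid$dims
  idx <- integer(nrow(pm))
  for (k in seq_len(nrow(pm))) {
    ij <- pmin(pmax(round(pm[k, ] / grid$dx), 0), dims - 1L)
    idx[k] <- sum(ij * cumprod(c(1L, dims[-length(dims)])))
  }
  as.integer(idx)
}

#' Simulate monodomain tissue
#'
#' Explicit forward-Euler integration of the monodomain
#' reaction-diffusion equation on a [tissue_grid], recording probe time
#' series, optional full-field voltage snapshots (1D/2D scalar grids)
#' and, on request, the heart-dipole vector (masked 3D grids).
#'
#' @param grid A [tissue_grid].
#' @param params An [ap_params()] set.
#' @param protocol A [stim_protocol()] / [stim_event()] or `NULL`.
#' @param duration Simulated time (ms).
#' @param dt Time step (ms, default 0.01); checked against
#'   [stability_limit()].
#' @param init Initial field (a prior `$state`), default all-resting.
#' @param probes Matrix of probe coordinates in cm (one row per probe),
#'   or for cables a vector of x positions.
#' @param record_dt Probe/dipole sampling interval (ms, default 1).
#' @param snapshot_dt Voltage frame interval (ms) or `NULL` for no
#'   frames.
#' @param snapshot_window Length-2 time window (ms) limiting frames.
#' @param dipole_center Length-3 center (cm) to record the dipole, or
#'   `NULL`.
#' @param t0 Start time (ms); stimulus times are absolute.
#' @param on_unstable `"abort"` (default) or `"warn"` when `dt` exceeds
#'   the stability bound.
#' @return A `tissue_run` list: `probes` (data.frame `time`, `p1`, ...),
#'   `state`, `frames` (nodes x frames matrix), `frame_t`, `dipole`
#'   (data.frame `time`, `Jx`, `Jy`, `Jz`), `t_end`, `grid`.
#' @export
simulate_tissue <- function(grid, params, protocol = NULL, duration,
                            dt = 0.01, init = NULL, probes = NULL,
                            record_dt = 1, snapshot_dt = NULL,
                            snapshot_window = NULL, dipole_center = NULL,
                            t0 = 0, on_unstable = c("abort", "warn")) {
  on_unstable <- match.arg(on_unstable)
  lim <- stability_limit(grid)
  if (dt >= lim) {
    msg <- sprintf("dt = %g ms violates the explicit stability bound %g ms",
                   dt, lim)
    if (on_unstable == "abort") stop(msg) else warning(msg)
  }
  nsteps <- as.integer(ceiling(duration / dt))
  rec_steps <- max(1L, as.integer(round(record_dt / dt)))
  events <- expand_events(protocol, grid)
  pidx <- probe_index(probes, grid)
  state <- init %||% resting_field(grid)

  fast <- is.null(grid$mask) && is.null(grid$fibers) && grid$ndim <= 2
  if (fast) {
    snap_steps <- if (is.null(snapshot_dt)) 0L
                  else max(1L, as.integer(round(snapshot_dt / dt)))
    win <- snapshot_window %||% c(t0, t0 + duration)
    out <- run_sheet_cpp(state, grid$dims[1],
                         if (grid$ndim == 2) grid$dims[2] else 1L,
                         grid$D, grid$dx, param_vec(params), dt, t0,
                         nsteps, events, pidx, rec_steps, snap_steps,
                         win[1], win[2])
    dip <- NULL
  } else {
    out <- run_voxel_cpp(state, grid$dims, grid$dx, grid_mask_vec(grid),
                         grid_tensor(grid), param_vec(params), dt, t0,
                         nsteps, events, pidx, rec_steps,
                         !is.null(dipole_center),
                         dipole_center %||% numeric(3))
    dip <- if (!is.null(dipole_center))
      data.frame(time = out$t, Jx = out$dipole[, 1],
                 Jy = out$dipole[, 2], Jz = out$dipole[, 3])
  }
  pr <- data.frame(time = out$t)
  if (length(pidx))
    for (q in seq_along(pidx)) pr[[paste0("p", q)]] <- out$probes[, q]
  structure(list(probes = pr, state = out$state,
                 frames = out$frames %||% NULL,
                 frame_t = out$frame_t %||% NULL,
                 dipole = dip, t_end = out$t_end, grid = grid,
                 params_label = params$label, dt = dt),
            class = "tissue_run")
}

#' @export
print.tissue_run <- function(x, ...) {
  cat("tissue_run [", x$params_label, "]: ", x$grid$ndim, "D, t_end = ",
      x$t_end, " ms, ", ncol(x$probes) - 1, " probe(s)", sep = "")
  if (!is.null(x$frames) && length(x$frames))
    cat(", ", length(x$frame_t), " frames", sep = "")
  cat("\n")
  invisible(x)
}

#' One explicit tissue step
#'
#' Convenience wrapper advancing a field state by a single `dt`.
#'
#' @inheritParams simulate_tissue
#' @param state Field state (list of V, h, f, r, s vectors).
#' @param t Current time (ms).
#' @return Updated field state.
#' @export
tissue_step <- function(state, grid, dt, protocol = NULL, t = 0, params) {
  run <- simulate_tissue(grid, params, protocol, duration = dt, dt = dt,
                         init = state, t0 = t, record_dt = dt)
  run$state
}
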