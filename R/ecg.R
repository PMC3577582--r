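#' Synthetic two-shell ventricle geometry
#'
#' A parametric stand-in for a real ventricular anatomy: two nested
#' truncated ellipsoidal shells (a thick-walled left ventricle and a
#' thin-walled right ventricle wrapped around its +x side) sharing a
#' septum, truncated by the basal (top z) face of the voxel box. The
#' endocardial surface (tissue voxels facing a cavity) is labeled and
#' split into three activation regions fired at 0, 5 and 10 ms, which
#' emulate the His-Purkinje conduction sequence: the basal half of the
#' septal endocardium (`A0`), the apical septal endocardium plus the
#' apical cap (`A5`), and the remaining free-wall endocardium (`A10`).
#' Fibers run circumferentially around the long (z) axis, giving a
#' transversely isotropic diffusion tensor.
#'
#' This geometry is synthetic: it reproduces the topology (two
#' cavities, shared septum, apex-to-base activation) and the voxel
#' resolution of a small mammalian ventricle model, not any measured
#' anatomy.
#'
#' @param nx,ny,nz Box dimensions in voxels (default 64 x 56 x 56).
#' @param dx Voxel size (cm, default 0.025).
#' @param lv_radius,lv_length Outer semi-axes of the left-ventricle
#'   ellipsoid (cm): equatorial radius and apex-to-base length.
#' @param lv_wall Left-ventricle wall thickness (cm).
#' @param rv_radius,rv_length,rv_wall Same for the right ventricle.
#' @param rv_shift Displacement of the right-ventricle center along +x
#'   (cm).
#' @param D_par,D_perp Diffusivities along/across fibers (cm^2/ms).
#' @return A `ventricle_geometry`: list with `grid` (a [voxel_grid()]
#'   with fibers), `regions` (named list `A0`, `A5`, `A10` of 1-based
#'   voxel indices), `endo` (all endocardial indices), `center` (tissue
#'   centroid, cm), `cavities` (list of cavity voxel indices).
#' @export
synthesize_ventricles <- function(nx = 64, ny = 56, nz = 56, dx = 0.025,
                                  lv_radius = 0.62, lv_length = 1.25,
                                  lv_wall = 0.18,
                                  rv_radius = 0.78, rv_length = 1.05,
                                  rv_wall = 0.08, rv_shift = 0.33,
                                  D_par = 1e-3, D_perp = 6.75e-5) {
  if (lv_wall <= 0 || rv_wall <= 0) stop("shell thickness must be > 0")
  co <- function(n) (seq_len(n) - 1) * dx
  x <- co(nx); y <- co(ny); z <- co(nz)
  Lz <- z[nz]
  cx <- 0.45 * x[nx]; cy <- 0.5 * y[ny]
  inside <- function(x0, y0, a, c) {
    # ellipsoid centered at (x0, y0, base), truncated by the box top
    xs <- (x - x0) / a; ys <- (y - y0) / a; zs <- (z - Lz) / c
    outer(outer(xs^2, ys^2, "+"), zs^2, "+") < 1
  }
  lv_out <- inside(cx, cy, lv_radius, lv_length)
  lv_in <- inside(cx, cy, lv_radius - lv_wall, lv_length - lv_wall)
  rv_out <- inside(cx + rv_shift, cy, rv_radius, rv_length)
  rv_in <- inside(cx + rv_shift, cy, rv_radius - rv_wall,
                  rv_length - rv_wall)
  mask <- (lv_out & !lv_in) | (rv_out & !rv_in & !lv_in)
  if (!any(mask)) stop("shells do not intersect the voxel box")
  lv_cav <- lv_in
  rv_cav <- rv_in & !lv_out
  if (!any(lv_cav) || !any(rv_cav))
    stop("degenerate geometry: a cavity is empty")

  # endocardium: tissue voxels 6-adjacent to a cavity voxel
  cav <- lv_cav | rv_cav
  nb_or <- function(a) {
    out <- array(FALSE, dim(a))
    out[-1, , ] <- out[-1, , ] | a[-nx, , ]
    out[-nx, , ] <- out[-nx, , ] | a[-1, , ]
    out[, -1, ] <- out[, -1, ] | a[, -ny, ]
    out[, -ny, ] <- out[, -ny, ] | a[, -1, ]
    out[, , -1] <- out[, , -1] | a[, , -nz]
    out[, , -nz] <- out[, , -nz] | a[, , -1]
    out
  }
  endo <- mask & nb_or(cav)
  endo_lv <- mask & nb_or(lv_cav)

  # septum: LV wall facing the RV cavity side. Early activation runs
  # along the LV-facing septal endocardium (as the His bundle does), so
  # the septum depolarizes left-to-right before the free walls fire.
  septum <- mask & lv_out & rv_out
  zc <- array(rep(z, each = nx * ny), c(nx, ny, nz))
  z_mid <- Lz - 0.5 * lv_length
  z_apex <- Lz - 0.85 * lv_length
  A0 <- endo_lv & septum & (zc >= z_mid)
  A5 <- endo_lv & ((septum & zc < z_mid) | (zc < z_apex))
  A5 <- A5 & !A0
  A10 <- endo & !A0 & !A5
  if (!any(A0) || !any(A5))
    stop("activation regions are empty; adjust shell parameters")

  # circumferential fibers around the long axis
  xg <- array(rep(x, ny * nz), c(nx, ny, nz))
  yg <- array(rep(rep(y, each = nx), nz), c(nx, ny, nz))
  fx <- -(yg - cy); fy <- xg - cx
  nrm <- sqrt(fx^2 + fy^2)
  fx <- ifelse(nrm > 0, fx / nrm, 1); fy <- ifelse(nrm > 0, fy / nrm, 0)
  fibers <- array(c(fx, fy, array(0, dim(fx))), c(nx, ny, nz, 3))

  grid <- voxel_grid(mask, dx, fibers = fibers, D_par = D_par,
                     D_perp = D_perp)
  idx <- which(mask)
  ctr <- c(mean(xg[idx]), mean(yg[idx]), mean(zc[idx]))
  structure(list(grid = grid,
                 regions = list(A0 = which(A0), A5 = which(A5),
                                A10 = which(A10)),
                 endo = which(endo), center = ctr,
                 cavities = list(lv = which(lv_cav), rv = which(rv_cav))),
            class = "ventricle_geometry")
}

#' @export
print.ventricle_geometry <- function(x, ...) {
  g <- x$grid
  cat("ventricle_geometry: ", paste(g$dims, collapse = " x "),
      " voxels (dx = ", g$dx, " cm), ", sum(g$mask), " in tissue\n",
      sep = "")
  cat("activation regions: A0 = ", length(x$regions$A0), ", A5 = ",
      length(x$regions$A5), ", A10 = ", length(x$regions$A10),
      " voxels\n", sep = "")
  cat(sprintf("center: (%.2f, %.2f, %.2f) cm\n", x$center[1],
              x$center[2], x$center[3]))
  invisible(x)
}

#' Endocardial activation-sequence protocol
#'
#' Per beat, suprathreshold 1-ms stimuli are delivered to the three
#' endocardial regions at offsets 0, 5 and 10 ms (base-to-mid septum,
#' mid-septum-to-apex, then the remaining fibers), emulating the fast
#' conduction system.
#'
#' @param geometry A [synthesize_ventricles()] geometry.
#' @param bcl Basic cycle length (ms, default 400).
#' @param beats Number of beats.
#' @param amplitude Stimulus amplitude (ms^-1).
#' @param offsets Firing offsets of the three regions within a beat
#'   (ms).
#' @param duration Stimulus duration (ms).
#' @return A [stim_protocol()] (empty regions are skipped).
#' @export
activation_protocol <- function(geometry, bcl = 400, beats = 1,
                                amplitude, offsets = c(0, 5, 10),
                                duration = 1) {
  evs <- list()
  for (k in seq_along(geometry$regions)) {
    idx <- geometry$regions[[k]]
    if (length(idx) == 0) next
    evs[[length(evs) + 1]] <-
      stim_event(idx, start = offsets[k], duration = duration,
                 amplitude = amplitude, bcl = bcl, n_beats = beats)
  }
  stim_protocol(evs)
}

#' Heart-dipole vector of a voltage snapshot
#'
#' Discrete equivalent of the volume integral of `r * div(D grad V)`:
#' the sum over tissue voxels of the conservative diffusion operator
#' (the same one the solver uses) weighted by the position relative to
#' the geometric center, times the voxel volume. Because the source
#' term sums to zero on a no-flux domain, the result does not depend on
#' the choice of center.
#'
#' @param V Voltage field (array or vector on the geometry grid).
#' @param geometry A `ventricle_geometry`.
#' @return Length-3 numeric vector (Jx, Jy, Jz), arbitrary units.
#' @export
heart_dipole <- function(V, geometry) {
  g <- geometry$grid
  rate <- as.numeric(diffusion_term(V, g))
  idx <- which(as.logical(g$mask))
  co <- arrayInd(idx, g$dims)
  r <- sweep((co - 1) * g$dx, 2, geometry$center)
  as.numeric(crossprod(r, rate[idx])) * g$dx^3
}

#' Pseudo-ECG of paced synthetic ventricles
#'
#' Runs the monodomain model on the ventricle geometry under the
#' endocardial activation sequence and records the heart-dipole vector
#' at 1 ms cadence, projected on one or more lead directions (default a
#' single "lead I" along the box x axis). Amplitudes are arbitrary
#' (homogeneous-torso monodomain approximation); use
#' [normalize_lead()] to scale a waveform to unit peak.
#'
#' @param geometry A [synthesize_ventricles()] geometry.
#' @param params An [ap_params()] set.
#' @param bcl Pacing period (ms, default 400).
#' @param beats Number of beats (default 2).
#' @param dt Time step (ms).
#' @param amplitude Stimulus amplitude; default 4x the single-cell
#'   threshold (endocardial surface voxels lose charge to their
#'   neighbors, so the margin is larger than in a single cell).
#' @param leads Named list of lead unit vectors. The box +x axis runs
#'   from the left toward the right ventricle, so the left-arm
#'   direction of the standard limb lead I is -x; override to taste.
#' @param record_dt Output cadence (ms).
#' @return An `ecg_trace` data.frame: `time`, `Jx`, `Jy`, `Jz`, one
#'   column per lead.
#' @export
pseudo_ecg <- function(geometry, params, bcl = 400, beats = 2, dt = 0.01,
                       amplitude = NULL, leads = list(I = c(-1, 0, 0)),
                       record_dt = 1) {
  amplitude <- amplitude %||%
    (4 * find_stimulus_threshold(params, dt))
  proto <- activation_protocol(geometry, bcl = bcl, beats = beats,
                               amplitude = amplitude)
  run <- simulate_tissue(geometry$grid, params, proto,
                         duration = bcl * beats, dt = dt,
                         record_dt = record_dt,
                         dipole_center = geometry$center)
  out <- run$dipole
  for (nm in names(leads)) {
    e <- leads[[nm]] / sqrt(sum(leads[[nm]]^2))
    out[[nm]] <- out$Jx * e[1] + out$Jy * e[2] + out$Jz * e[3]
  }
  structure(out, class = c("ecg_trace", "data.frame"), bcl = bcl,
            beats = beats, params_label = params$label)
}

#' Scale a lead waveform to unit peak absolute deflection
#' @param x Numeric lead signal.
#' @return `x / max(abs(x))` (unchanged if identically zero).
#' @export
normalize_lead <- function(x) {
  m <- max(abs(x))
  if (m == 0) x else x / m
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat("pseudo-ECG [", attr(x, "params_label"), "]: ",
      attr(x, "beats"), " beat(s) at BCL = ", attr(x, "bcl"),
      " ms, leads: ",
      paste(setdiff(names(x), c("time", "Jx", "Jy", "Jz")),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.ecg_trace <- function(x, lead = NULL, ...) {
  lead <- lead %||% setdiff(names(x), c("time", "Jx", "Jy", "Jz"))[1]
  plot(x$time, normalize_lead(x[[lead]]), type = "l",
       xlab = "time (ms)", ylab = paste("lead", lead, "(normalized)"),
       ...)
  invisible(x)
}

#' Read/write a ventricle geometry container
#'
#' The geometry travels as R's native serialized container holding the
#' documented fields (dims, dx, mask, fiber field, region labels,
#' center), so user-supplied anatomies can be dropped in.
#'
#' @param geometry A `ventricle_geometry`.
#' @param path File path (`.rds`).
#' @return `read_geometry` returns the `ventricle_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "ventricle_geometry"))
  saveRDS(geometry, path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- readRDS(path)
  if (!inherits(g, "ventricle_geometry"))
    stop("not a ventricle_geometry container: ", path)
  g
}
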