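test_that("stimulus threshold brackets excitation for every built-in set", {
  for (set in param_sets()) {
    p <- builtin_params(set)
    thr <- set_threshold(set)
    excites <- function(a) {
      tr <- simulate_cell(p, cell_pacing(a, n_beats = 1), duration = 21,
                          record_dt = 0.1)
      max(tr$V) > 0.8
    }
    expect_true(excites(1.5 * thr))
    expect_false(excites(0.5 * thr))
  }
})

test_that("excitation is monotone in stimulus amplitude", {
  p <- builtin_params("lrd")
  thr <- set_threshold("lrd")
  outcome <- vapply(seq(0.05, 2.5, length.out = 50) * thr, function(a) {
    tr <- simulate_cell(p, cell_pacing(a, n_beats = 1), duration = 21,
                        record_dt = 0.1)
    max(tr$V) > 0.8
  }, TRUE)
  expect_false(outcome[1])
  expect_true(outcome[50])
  expect_identical(sum(diff(outcome) != 0), 1L)  # one switch, no re-entry
})

test_that("upper-bracket failure raises", {
  p <- builtin_params("lrd")
  expect_error(find_stimulus_threshold(p, upper = 1e-4), "fails to excite")
})

test_that("measure_apd recovers constructed pulse geometry", {
  t <- 0:600
  ramp <- function(t, t0) pmin(1, pmax(0, (t - t0) / 2))
  v <- ramp(t, 100) * (1 - ramp(t, 300))  # up ramp at 100, down at 300
  ap <- measure_apd(data.frame(time = t, V = v), threshold = 0.5)
  # symmetric 2 ms ramps cross V = 0.5 exactly at their midpoints
  expect_equal(ap$t_up, 101)
  expect_equal(ap$t_down, 301)
  expect_equal(ap$apd, 200)
  # constant subthreshold trace: no beats, no error
  expect_identical(nrow(measure_apd(data.frame(time = t, V = rep(0.05, 601)))),
                   0L)
})

test_that("APD + DI = BCL at steady pacing", {
  p <- builtin_params("epi")
  amp <- 1.5 * set_threshold("epi")
  tr <- simulate_cell(p, cell_pacing(amp, bcl = 500, n_beats = 5),
                      duration = 2500, record_dt = 0.5)
  ap <- measure_apd(tr)
  expect_identical(nrow(ap), 5L)
  cyc <- ap$apd[-5] + ap$di[-1]
  expect_true(all(abs(cyc - 500) <= 1))
})

test_that("dynamic APD restitution is monotone and drops blocked rates", {
  p <- builtin_params("epi")
  amp <- 1.5 * set_threshold("epi")
  rc <- apd_restitution(p, c(320, 400, 500, 700, 1000), beats = 8,
                        amplitude = amp)
  expect_true(all(rc$captured))
  ord <- order(rc$di)
  expect_true(all(diff(rc$apd[ord]) >= 0))
  expect_gt(rc$apd[rc$bcl == 1000], rc$apd[rc$bcl == 500])
  # below refractoriness: flagged, not raised
  rc2 <- apd_restitution(p, c(240, 1000), beats = 8, amplitude = amp)
  expect_false(rc2$captured[1])
  expect_true(is.na(rc2$apd[1]))
  expect_true(rc2$captured[2])
})

test_that("CV restitution guards its probe layout and failure mode", {
  p <- builtin_params("lrd")
  expect_error(cv_restitution(p, 1000, probes = c(0.5, 5),
                              amplitude = 1), "1 cm")
  # a subthreshold stimulus never reaches the distal probe
  expect_error(cv_restitution(p, 400, cable_length = 3,
                              probes = c(1, 2), beats = 1,
                              amplitude = 0.01), "distal")
})

test_that("tip tracking pinpoints the singularity of an analytic rotating field", {
  g <- sheet_grid(2, 2, 0.02)
  nx <- g$dims[1]
  co <- (seq_len(nx) - 1) * g$dx - 1          # centered coordinates
  xg <- matrix(co, nx, nx); yg <- t(xg)
  th <- atan2(yg, xg); rr <- sqrt(xg^2 + yg^2)
  omega <- 2 * pi / 100                        # one turn per 100 ms
  frame <- function(t) as.numeric(rr * cos(th - omega * t))
  times <- seq(0, 40, by = 2)
  frames <- vapply(times, frame, numeric(nx * nx))
  tips <- track_spiral_tip(frames, times, g, V_iso = 0)
  expect_identical(nrow(tips), length(times) - 1L)
  # recovered within one grid cell of the rotation center (1, 1)
  expect_true(all(abs(tips$x - 1) <= g$dx))
  expect_true(all(abs(tips$y - 1) <= g$dx))
})

test_that("tip chirality follows the frame order", {
  g <- sheet_grid(2, 2, 0.02)
  nx <- g$dims[1]
  co <- (seq_len(nx) - 1) * g$dx - 1
  xg <- matrix(co, nx, nx); yg <- t(xg)
  th <- atan2(yg, xg); rr <- sqrt(xg^2 + yg^2)
  omega <- 2 * pi / 100
  frame <- function(t) as.numeric(rr * cos(th - omega * t))
  times <- seq(0, 60, by = 2)
  frames <- vapply(times, frame, numeric(nx * nx))
  # with a nonzero iso level the detected point orbits the center
  orbit_sign <- function(fr, tm) {
    tp <- track_spiral_tip(fr, tm, g, V_iso = 0.3)
    x <- tp$x - 1; y <- tp$y - 1
    sum(x[-nrow(tp)] * y[-1] - x[-1] * y[-nrow(tp)])
  }
  fwd <- orbit_sign(frames, times)
  rev <- orbit_sign(frames[, ncol(frames):1], times)
  expect_gt(abs(fwd), 0)
  expect_lt(fwd * rev, 0)
})

test_that("plane waves contain no interior phase singularity", {
  g <- sheet_grid(2, 2, 0.02)
  nx <- g$dims[1]
  co <- (seq_len(nx) - 1) * g$dx
  front <- function(t) {
    prof <- 0.5 * (1 - tanh((co - 0.05 * t - 0.5) / 0.1))
    as.numeric(matrix(prof, nx, nx))
  }
  times <- seq(0, 20, by = 2)
  frames <- vapply(times, front, numeric(nx * nx))
  tips <- track_spiral_tip(frames, times, g, V_iso = 0.5)
  expect_identical(nrow(tips), 0L)
})

test_that("spiral statistics recover an exact synthetic period", {
  t <- seq(0, 1600, by = 0.5)
  v <- as.numeric(t %% 100 < 30)
  st <- spiral_statistics(data.frame(time = t, V = v), threshold = 0.5,
                          discard = 500)
  expect_equal(st$T, 100)
  expect_equal(st$APD + st$DI, st$T, tolerance = 1e-9)
  expect_true(all(abs(st$rotations$T -
                        (st$rotations$apd + st$rotations$di)) < 1e-9))
  # too few rotations raises
  short <- data.frame(time = seq(0, 800, 0.5),
                      v = as.numeric(seq(0, 800, 0.5) %% 100 < 30))
  expect_error(spiral_statistics(short, 0.5, discard = 500,
                                 min_rotations = 5), "rotations")
})
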