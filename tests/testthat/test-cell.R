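test_that("steady-state gate values follow the piecewise formulas", {
  lrd <- builtin_params("lrd")  # V_c = 0.38, V_1 = 0.453, V_r = 0.6
  ss0 <- steady_state_gates(0, lrd)
  expect_identical(ss0$m_inf, 0)
  expect_identical(ss0$h_inf, 1)
  expect_identical(ss0$d_inf, 0)
  expect_identical(ss0$k_inf, 0)
  expect_identical(ss0$r_inf, 0)
  expect_identical(ss0$s_inf, 1)
  # tanh(0) = 0 makes the slow-inward activation half-open at V_1
  expect_equal(steady_state_gates(lrd$V_1, lrd)$d_inf, 0.5)
  # slow-outward saturation: linear below V_c, saturated above
  expect_equal(steady_state_gates(0.19, lrd)$k_inf, 0.5)
  for (v in c(0.38, 0.5, 1, 1.4))
    expect_identical(steady_state_gates(v, lrd)$k_inf, 1)
  # independently evaluated sigmoid (exp form) at rest
  x <- 2 * lrd$beta_2 * (0 - lrd$V_2)
  expect_equal(steady_state_gates(0, lrd)$fprime_inf,
               1 / (1 + exp(x)), tolerance = 1e-12)
  expect_equal(steady_state_gates(0, lrd)$fprime_inf, 0.9999734,
               tolerance = 1e-6)
  # ranges over the physiological span: everything but m_inf in [0, 1]
  ss <- steady_state_gates(seq(0, 1.5, by = 0.01), lrd)
  expect_true(all(ss$m_inf >= 0))
  expect_true(all(ss[setdiff(names(ss), "m_inf")] >= 0 &
                    ss[setdiff(names(ss), "m_inf")] <= 1))
})

test_that("gate time constants switch between their two values", {
  tnnp <- builtin_params("tnnp")
  lo <- gate_time_constants(0, tnnp)
  expect_equal(unlist(lo), c(tau_h = 90.5, tau_f = 43.1, tau_r = 2.2,
                             tau_s = 99.9))
  hi <- gate_time_constants(1, tnnp)
  expect_equal(unlist(hi), c(tau_h = 6.61, tau_f = 181, tau_r = 13.5,
                             tau_s = 4.34))
  # discontinuous jump at V_c, with the convention Theta(0) = 1
  eps <- 1e-12
  for (set in param_sets()) {
    p <- builtin_params(set)
    expect_identical(gate_time_constants(p$V_c - eps, p)$tau_h,
                     p$tau_h_plus)
    expect_equal(gate_time_constants(p$V_c, p)$tau_h, p$tau_h_minus)
  }
  expect_true(all(unlist(gate_time_constants(seq(-1, 2, 0.1), tnnp)) > 0))
})

test_that("membrane currents match the closed forms and sign structure", {
  for (set in param_sets()) {
    p <- builtin_params(set)
    J <- membrane_currents(resting_state(), p)
    expect_identical(unlist(J), c(J_fi = 0, J_si = 0, J_so = 0, J_to = 0))
    # slow outward saturates at g_so above threshold
    st <- cell_state(V = p$V_c + 0.1, r = 0)
    expect_identical(membrane_currents(st, p)$J_so, p$g_so)
  }
  lrd <- builtin_params("lrd")
  # hand-evaluated fast inward current at V = 1, h = 1
  J <- membrane_currents(cell_state(V = 1), lrd)
  expect_equal(J$J_fi, -10 * (1 - 0.38) * (1.2 - 1))
  # sign structure across a voltage sweep
  for (v in seq(-0.2, 1.6, by = 0.1)) {
    st <- cell_state(V = v, h = 0.5, f = 0.5, r = 0.5, s = 0.5)
    J <- membrane_currents(st, lrd)
    expect_lte(J$J_si, 0)
    if (v <= lrd$V_fi) expect_lte(J$J_fi, 0)
    if (v >= lrd$V_to) {
      expect_gte(J$J_so, 0)
      expect_gte(J$J_to, 0)
    }
  }
})

test_that("the resting state is an exact fixed point that attracts", {
  for (set in param_sets()) {
    p <- builtin_params(set)
    expect_identical(as.numeric(cell_rhs(resting_state(), 0, p)),
                     rep(0, 5))
    expect_identical(unclass(cell_step(resting_state(), 0.01, 0, p)),
                     unclass(resting_state()))
    # small perturbations decay back to rest
    pert <- cell_state(V = 0.01, h = 0.99, f = 0.99, r = 0.01, s = 0.99)
    tr <- simulate_cell(p, duration = 1500, init = pert,
                        record_gates = TRUE)
    fin <- attr(tr, "state")
    expect_equal(as.numeric(fin), as.numeric(resting_state()),
                 tolerance = 2e-3)
  }
})

test_that("cell_rhs bookkeeping: stimulus sign and reversal potential", {
  p <- builtin_params("epi")
  expect_equal(cell_rhs(resting_state(), 0.5, p)[["V"]], 0.5)
  # at V = V_fi the fast inward current vanishes (reversal)
  st <- cell_state(V = p$V_fi, h = 0.8, f = 0.5, r = 0.5, s = 0.5)
  expect_identical(membrane_currents(st, p)$J_fi, 0)
  # Euler arithmetic of one step from rest under stimulus
  stepped <- cell_step(resting_state(), 0.01, 0.5, p)
  expect_equal(stepped[["V"]], 0.005)
  expect_identical(as.numeric(stepped)[-1],
                   as.numeric(resting_state())[-1])
  expect_error(cell_step(resting_state(), 0, 0, p), "dt")
  expect_error(cell_step(resting_state(), -0.01, 0, p), "dt")
})

test_that("compiled stepper agrees with the pure-R Euler reference", {
  p <- builtin_params("mcell")
  amp <- 2 * set_threshold("mcell")
  nsteps <- 20000  # 200 ms through a full AP
  ref <- r_euler_cell(p, 0.01, nsteps,
                      stim = function(t) if (t < 1) amp else 0)
  tr <- simulate_cell(p, cell_pacing(amp, n_beats = 1), duration = 200,
                      dt = 0.01, record_dt = 0.01, record_gates = TRUE)
  # tabulated slow-inward factor in the kernel: agreement to ~1e-5
  expect_lt(max(abs(tr$V - ref[, "V"])), 1e-5)
  expect_lt(max(abs(tr$h - ref[, "h"])), 1e-6)
  expect_lt(max(abs(tr$f - ref[, "f"])), 1e-6)
  expect_lt(max(abs(tr$s - ref[, "s"])), 1e-6)
})

test_that("gates stay in [0,1] over a million paced steps", {
  p <- builtin_params("epi")
  amp <- 1.5 * set_threshold("epi")
  tr <- simulate_cell(p, cell_pacing(amp, bcl = 500, n_beats = 20),
                      duration = 10000, dt = 0.01, record_dt = 0.01,
                      record_gates = TRUE)
  g <- as.matrix(tr[c("h", "f", "r", "s")])
  expect_gte(min(g), 0)
  expect_lte(max(g), 1)
})

test_that("voltage is pulled down whenever it exceeds the sodium reversal", {
  # drive V above V_fi with a strong pulse, then release: in the
  # unstimulated stretch dV/dt must stay negative while V > V_fi
  for (set in param_sets()) {
    p <- builtin_params(set)
    tr <- simulate_cell(p, cell_pacing(20, n_beats = 1, duration = 8),
                        duration = 100, record_dt = 0.1)
    expect_gt(max(tr$V), p$V_fi)  # overshoot achieved
    high <- which(tr$time[-1] > 8 & tr$V[-1] > p$V_fi)
    expect_true(all(diff(tr$V)[high] < 0))
  }
})

test_that("zero and subthreshold stimuli do not excite", {
  p <- builtin_params("lrd")
  tr0 <- simulate_cell(p, cell_pacing(0, n_beats = 1), duration = 100)
  expect_identical(unique(tr0$V), 0)
  thr <- set_threshold("lrd")
  trs <- simulate_cell(p, cell_pacing(0.2 * thr, n_beats = 1),
                       duration = 100, record_dt = 0.1)
  expect_lt(max(trs$V), p$V_c)
})

test_that("Euler APD converges first order under dt halving", {
  p <- builtin_params("lrd")
  amp <- 1.5 * set_threshold("lrd")
  apd_at <- function(dtv) {
    tr <- simulate_cell(p, cell_pacing(amp, bcl = 600, n_beats = 2),
                        duration = 1200, dt = dtv, record_dt = 0.1)
    measure_apd(tr)$apd[2]
  }
  a1 <- apd_at(0.01); a2 <- apd_at(0.005); a3 <- apd_at(0.0025)
  expect_lt(abs(a1 - a2), 1)            # dt halving moves APD < 1 ms
  expect_lt(abs(a2 - a3), abs(a1 - a2)) # differences shrink
  # successive differences shrink roughly by the first-order factor 2
  expect_equal(abs(a1 - a2) / abs(a2 - a3), 2, tolerance = 0.5)
})

test_that("paced AP matches an adaptive-step reference integration", {
  skip_if_not_installed("deSolve")
  p <- builtin_params("epi")
  amp <- 1.5 * set_threshold("epi")
  rhs <- function(t, y, parms) {
    st <- structure(y, names = c("V", "h", "f", "r", "s"),
                    class = "cell_state")
    list(as.numeric(cell_rhs(st, if (t %% 1000 < 1) amp else 0, p)))
  }
  times <- seq(0, 2000, by = 0.5)
  sol <- deSolve::lsoda(as.numeric(resting_state()), times, rhs,
                        rtol = 1e-8, atol = 1e-8, hmax = 0.5)
  tr <- simulate_cell(p, cell_pacing(amp, bcl = 1000, n_beats = 2),
                      duration = 2000, dt = 0.0025, record_dt = 0.5)
  # agreement within 1 mV equivalent (0.01 dimensionless) everywhere
  expect_lt(max(abs(tr$V - sol[, 2])), 0.01)
})

test_that("per-sample voltage update equals minus total current plus stimulus", {
  p <- builtin_params("endo")
  amp <- 1.5 * set_threshold("endo")
  tr <- simulate_cell(p, cell_pacing(amp, n_beats = 1), duration = 50,
                      dt = 0.01, record_dt = 0.01, record_gates = TRUE)
  n <- nrow(tr) - 1
  ionic <- vapply(seq_len(n), function(k) {
    st <- cell_state(tr$V[k], tr$h[k], tr$f[k], tr$r[k], tr$s[k])
    sum(unlist(membrane_currents(st, p)))
  }, 0)
  stim <- ifelse(tr$time[seq_len(n)] < 1, amp, 0)
  lhs <- diff(tr$V) / 0.01
  expect_equal(lhs, -ionic + stim, tolerance = 1e-4)
})
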