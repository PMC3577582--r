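p_epi <- builtin_params("epi")
amp_epi <- 1.5 * set_threshold("epi")

test_that("objective is exactly zero on self-generated templates", {
  tpl <- paced_template(p_epi, 600, amp_epi, beats = 6)
  pb <- fit_problem(list(tpl))
  res <- ap_objective(p_epi, pb, pre_beats = 6,
                      stim_amplitude = amp_epi)
  expect_identical(max(abs(res)), 0)
})

test_that("residual bookkeeping: lengths and weight linearity", {
  t1 <- paced_template(p_epi, 600, amp_epi, beats = 4)
  t2 <- paced_template(p_epi, 900, amp_epi, beats = 4)
  cvt <- data.frame(bcl = 800, cv = 55)
  pb <- fit_problem(list(t1, t2), cv_targets = cvt)
  other <- modify_params(p_epi, g_si = 0.2)
  res <- ap_objective(other, pb, pre_beats = 4, stim_amplitude = amp_epi)
  expect_identical(length(res), length(t1$time) + length(t2$time) + 1L)
  # doubling the notch weight doubles exactly the in-notch residuals
  pb2 <- fit_problem(list(t1, t2), cv_targets = cvt, notch_weight = 6)
  res2 <- ap_objective(other, pb2, pre_beats = 4,
                       stim_amplitude = amp_epi)
  ratio <- res2 / res
  ratio[!is.finite(ratio)] <- NA
  expect_true(all(ratio %in% c(1, 2) | is.na(ratio)))
  expect_true(any(ratio == 2, na.rm = TRUE))
})

test_that("millivolt templates are detected and converted", {
  tpl <- paced_template(p_epi, 600, amp_epi, beats = 4)
  tpl_mV <- list(bcl = 600, time = tpl$time, V = to_millivolts(tpl$V))
  pb <- fit_problem(list(tpl_mV))
  expect_equal(pb$templates[[1]]$V, tpl$V, tolerance = 1e-12)
})

test_that("a fully frozen fit returns the start and its cost", {
  tpl <- paced_template(p_epi, 600, amp_epi, beats = 4)
  pb <- fit_problem(list(tpl))
  start <- modify_params(p_epi, g_si = 0.19)
  fit <- fit_ap_model(pb, start, free = character(0), pre_beats = 4,
                      stim_amplitude = amp_epi)
  expect_identical(fit$params, start)
  expect_equal(fit$cost,
               sum(ap_objective(start, pb, pre_beats = 4,
                                stim_amplitude = amp_epi)^2))
})

test_that("truth is a local minimum of the self-fit cost", {
  tpl <- paced_template(p_epi, 500, amp_epi, beats = 5)
  pb <- fit_problem(list(tpl,
                         paced_template(p_epi, 900, amp_epi, beats = 5)))
  cost <- function(prm) sum(ap_objective(prm, pb, pre_beats = 5,
                                         stim_amplitude = amp_epi)^2)
  c0 <- cost(p_epi)
  for (nm in c("g_fi", "g_si", "g_to", "tau_f_minus")) {
    for (fac in c(0.99, 1.01)) {
      mod <- setNames(list(unclass(p_epi)[[nm]] * fac), nm)
      expect_gt(cost(do.call(modify_params, c(list(p_epi), mod))), c0)
    }
  }
})

test_that("fitting is deterministic given the seed", {
  tpl <- paced_template(p_epi, 500, amp_epi, beats = 4)
  pb <- fit_problem(list(tpl))
  start <- modify_params(p_epi, g_si = 0.2, g_to = 1.8)
  run <- function() fit_ap_model(pb, start, free = c("g_si", "g_to"),
                                 pre_beats = 4, n_starts = 2, seed = 99,
                                 stim_amplitude = amp_epi,
                                 control = list(maxiter = 4,
                                                epsfcn = 1e-4))
  f1 <- run(); f2 <- run()
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$cost, f2$cost)
})

test_that("notch weighting reduces the notch-depth error", {
  # template with an artificially deepened phase-1 notch
  tpl <- paced_template(p_epi, 600, amp_epi, beats = 5)
  up <- fourcurrent:::upstroke_time(tpl$time, tpl$V)
  bump <- 0.08 * exp(-((tpl$time - up - 20) / 8)^2)
  tpl$V <- tpl$V - bump
  notch_depth <- function(v) min(v[tpl$time > up + 5 &
                                    tpl$time < up + 60])
  target_depth <- notch_depth(tpl$V)
  start <- modify_params(p_epi, g_to = 1.5)
  fit_with <- function(w) {
    pb <- fit_problem(list(tpl), notch_weight = w)
    fit <- fit_ap_model(pb, start, free = c("g_to", "tau_s_minus"),
                        pre_beats = 5, stim_amplitude = amp_epi,
                        control = list(maxiter = 20, epsfcn = 1e-4))
    tr <- simulate_cell(fit$params,
                        cell_pacing(amp_epi, bcl = 600, n_beats = 5),
                        duration = 3000, record_dt = 1)
    sel <- tr$time >= 4 * 600 - 5
    abs(notch_depth(approx(tr$time[sel] - (4 * 600 - 5), tr$V[sel],
                           tpl$time, rule = 2)$y) - target_depth)
  }
  expect_lte(fit_with(3), fit_with(1) + 1e-9)
})
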