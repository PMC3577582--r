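# Shared fixtures, built in code. Thresholds of the built-in sets are
# cached per session because the bisection is deterministic and several
# tests need them.

.thr_cache <- new.env(parent = emptyenv())

set_threshold <- function(set) {
  if (is.null(.thr_cache[[set]]))
    .thr_cache[[set]] <- find_stimulus_threshold(builtin_params(set))
  .thr_cache[[set]]
}

# steady-state paced template of a built-in set, as used by the
# fitting tests (final beat, from 5 ms before the stimulus)
paced_template <- function(params, bcl, amplitude, beats = 10) {
  tr <- simulate_cell(params,
                      cell_pacing(amplitude, bcl = bcl, n_beats = beats),
                      duration = bcl * beats, record_dt = 1)
  sel <- tr$time >= (beats - 1) * bcl - 5
  list(bcl = bcl, time = tr$time[sel] - ((beats - 1) * bcl - 5),
       V = tr$V[sel])
}

# pure-R forward-Euler reference stepper (independent of the C++ path)
r_euler_cell <- function(params, dt, nsteps, stim = function(t) 0,
                         state = resting_state()) {
  out <- matrix(NA_real_, nsteps + 1, 5,
                dimnames = list(NULL, c("V", "h", "f", "r", "s")))
  out[1, ] <- unclass(state)
  for (k in seq_len(nsteps)) {
    t <- (k - 1) * dt
    state <- cell_step(state, dt, stim(t), params)
    out[k + 1, ] <- unclass(state)
  }
  out
}
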