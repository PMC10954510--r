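# Fixtures built in code: analytic sinusoidal tachograms and random
# parameter sets used across test files.

# beat series whose RR follows rr_fun(t) exactly, onsets advanced by the
# current RR as in the generator
sinusoid_beats <- function(duration_s, rr_fun) {
  t <- 0
  times <- numeric(0)
  rr <- numeric(0)
  while (t < duration_s) {
    r <- rr_fun(t)
    times <- c(times, t)
    rr <- c(rr, r)
    t <- t + r / 1000
  }
  beat_series(times, rr)
}

# random valid parameter sets with fluctuations, for property tests
random_param_sets <- function(n, seed = 42) {
  withr::with_seed(seed, {
    tsys <- stats::runif(n, 0, 600)
    th <- stats::runif(n, -50, -30)
    mp <- th - stats::runif(n, 5, 40)        # strictly below threshold
    m <- stats::runif(n, 0.01, 0.08)
    dmp <- stats::runif(n, 0, 1) * (th - mp) * 0.8
    dm <- stats::runif(n, 0, 1) * m * 0.8
    sinus_params(tsys = tsys, th = th, mp = mp, m = m, dmp = dmp, dm = dm)
  })
}

control_params <- function() sinus_params()

lf_only_mod <- function() modulation_spec(mp_lf_amp = 2, m_lf_amp = 0.002)
hf_only_mod <- function() modulation_spec(mp_hf_amp = 2)
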