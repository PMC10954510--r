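#' Beat series constructor
#'
#' A beat series is a tibble with one row per beat: `time_s`, the beat onset
#' in seconds from record start (strictly increasing); `rr_ms`, the heart
#' period (RR interval) beginning at that onset, in ms; and `valid`, a
#' logical normal-beat flag (FALSE marks artifacts / ectopy). For series
#' produced by [simulate_beats()], `diff(time_s)` equals `rr_ms/1000` of the
#' earlier beat by construction.
#'
#' @param time_s Beat onset times in seconds, strictly increasing.
#' @param rr_ms Heart periods in ms, all positive.
#' @param valid Logical validity flags (recycled).
#' @param meta Optional named list of provenance attributes.
#'
#' @return A tibble of class `beat_series`.
#' @export
beat_series <- function(time_s, rr_ms, valid = TRUE, meta = list()) {
  b <- tibble::tibble(time_s = as.numeric(time_s),
                      rr_ms = as.numeric(rr_ms),
                      valid = rep_len(as.logical(valid), length(time_s)))
  validate_beat_series(b)
  structure(b, class = c("beat_series", class(b)), meta = meta)
}

#' @rdname beat_series
#' @param x A data frame with columns `time_s`, `rr_ms` and optionally
#'   `valid`.
#' @export
as_beat_series <- function(x) {
  x <- tibble::as_tibble(x)
  if (is.null(x$valid)) x$valid <- TRUE
  beat_series(x$time_s, x$rr_ms, x$valid, meta = attr(x, "meta") %||% list())
}

validate_beat_series <- function(b) {
  if (nrow(b) == 0) rlang::abort("empty beat series")
  if (any(!is.finite(b$rr_ms)) || any(b$rr_ms <= 0)) {
    rlang::abort("rr_ms must be positive and finite")
  }
  if (nrow(b) > 1 && any(diff(b$time_s) <= 0)) {
    rlang::abort("time_s must be strictly increasing")
  }
  invisible(b)
}

#' Autonomic modulation specification
#'
#' Describes sinusoidal low-frequency (LF, baroreflex-range, ~0.1 Hz) and
#' high-frequency (HF, respiratory-range, ~0.25 Hz) modulation of the
#' sinoatrial parameters `mp` and `m`. Amplitudes are half-amplitudes in the
#' units of the modulated parameter. By default the HF slope amplitude
#' `m_hf_amp` is 0 and should stay 0: intracellular cAMP, which carries slope
#' modulation, is too sluggish to follow respiratory-frequency drive.
#' Setting it nonzero is an explicit departure from the framework.
#'
#' @param lf_freq LF modulation frequency, Hz (in `[0.04, 0.15)`).
#' @param hf_freq HF modulation frequency, Hz (in `[0.15, 0.4)`).
#' @param mp_lf_amp,mp_hf_amp Membrane-potential modulation half-amplitudes, mV.
#' @param m_lf_amp,m_hf_amp Slope modulation half-amplitudes, mV/ms.
#' @param lf_phase,hf_phase Phase offsets, radians.
#'
#' @return A list of class `modulation_spec`.
#' @examples
#' modulation_spec(mp_lf_amp = 2, m_lf_amp = 0.002)  # LF-only drive
#' @export
modulation_spec <- function(lf_freq = 0.1, hf_freq = 0.25,
                            mp_lf_amp = 0, mp_hf_amp = 0,
                            m_lf_amp = 0, m_hf_amp = 0,
                            lf_phase = 0, hf_phase = 0) {
  if (lf_freq < 0.04 || lf_freq >= 0.15) {
    rlang::abort("lf_freq must lie in the LF band [0.04, 0.15) Hz")
  }
  if (hf_freq < 0.15 || hf_freq >= 0.4) {
    rlang::abort("hf_freq must lie in the HF band [0.15, 0.4) Hz")
  }
  amps <- c(mp_lf_amp, mp_hf_amp, m_lf_amp, m_hf_amp)
  if (any(amps < 0)) rlang::abort("modulation amplitudes must be >= 0")
  structure(list(lf_freq = lf_freq, hf_freq = hf_freq,
                 mp_lf_amp = mp_lf_amp, mp_hf_amp = mp_hf_amp,
                 m_lf_amp = m_lf_amp, m_hf_amp = m_hf_amp,
                 lf_phase = lf_phase, hf_phase = hf_phase),
            class = "modulation_spec")
}

#' Simulate a beat series from the automaticity model
#'
#' Generates beats iteratively: at each onset `t` the instantaneous
#' parameters are
#' `mp(t) = mp + mp_lf_amp*sin(2*pi*lf_freq*t + lf_phase) + mp_hf_amp*sin(2*pi*hf_freq*t + hf_phase)`
#' and analogously for `m(t)`; the beat's heart period is the closed-form
#' period at `(mp(t), m(t))` and the next onset follows one period later.
#' Modulation is sampled at beat onsets, not integrated over the beat. The
#' generator is deterministic; randomness enters only through
#' [inject_artifacts()].
#'
#' @param params A one-row data frame of base parameters ([sinus_params()]).
#' @param mod A [modulation_spec()].
#' @param duration_s Record duration in seconds (> 0); beats are generated
#'   while the onset lies before `duration_s`.
#'
#' @return A [beat_series()] with all beats flagged valid.
#' @examples
#' b <- simulate_beats(sinus_params(),
#'                     modulation_spec(mp_lf_amp = 2, m_lf_amp = 0.002),
#'                     duration_s = 120)
#' range(b$rr_ms)
#' @export
simulate_beats <- function(params, mod = modulation_spec(), duration_s) {
  params <- tibble::as_tibble(params)
  stopifnot(nrow(params) == 1, duration_s > 0)
  validate_sinus_params(params)
  # worst-case excursions must keep the cell firing
  mp_max <- params$mp + mod$mp_lf_amp + mod$mp_hf_amp
  m_min <- params$m - mod$m_lf_amp - mod$m_hf_amp
  if (mp_max >= params$th || m_min <= 0) {
    rlang::abort("modulation amplitudes drive parameters outside model validity")
  }

  n_guess <- ceiling(duration_s * 1000 / heart_period(params)$hp_ms * 1.5) + 8
  times <- numeric(n_guess)
  rr <- numeric(n_guess)
  t <- 0
  i <- 0
  while (t < duration_s) {
    mp_t <- params$mp +
      mod$mp_lf_amp * sin(2 * pi * mod$lf_freq * t + mod$lf_phase) +
      mod$mp_hf_amp * sin(2 * pi * mod$hf_freq * t + mod$hf_phase)
    m_t <- params$m +
      mod$m_lf_amp * sin(2 * pi * mod$lf_freq * t + mod$lf_phase) +
      mod$m_hf_amp * sin(2 * pi * mod$hf_freq * t + mod$hf_phase)
    if (mp_t >= params$th || m_t <= 0) {
      rlang::abort(sprintf(
        "model validity violated at beat time %.3f s (mp = %.2f, m = %.4f)",
        t, mp_t, m_t))
    }
    i <- i + 1
    times[i] <- t
    rr[i] <- params$tsys + (params$th - mp_t) / m_t
    t <- t + rr[i] / 1000
  }
  beat_series(times[seq_len(i)], rr[seq_len(i)],
              meta = list(source = "synthetic",
                          params = params, modulation = mod,
                          duration_s = duration_s))
}

#' Scenario-driven beat simulation
#'
#' Simulates a beat series under one of the preset autonomic scenarios
#' ([scenario_presets()]), driving `mp` with the shared 2 mV fluctuation at
#' both LF and HF and `m` with the scenario's LF slope fluctuation only (the
#' HF slope amplitude is 0 by model assumption).
#'
#' @param scenario One of `"control"`, `"high_sna_low_pna"`,
#'   `"low_sna_high_pna"`.
#' @param duration_s Record duration in seconds.
#' @param bands Which modulation components to enable: `"both"` (default),
#'   `"lf"` or `"hf"`.
#' @return A [beat_series()].
#' @export
simulate_scenario <- function(scenario = scenario_names(), duration_s = 600,
                              bands = c("both", "lf", "hf")) {
  scenario <- match.arg(scenario)
  bands <- match.arg(bands)
  pre <- scenario_presets()
  lf <- pre[pre$scenario == scenario & pre$band == "lf", ]
  mod <- modulation_spec(
    mp_lf_amp = if (bands %in% c("both", "lf")) lf$dmp else 0,
    m_lf_amp = if (bands %in% c("both", "lf")) lf$dm else 0,
    mp_hf_amp = if (bands %in% c("both", "hf")) lf$dmp else 0
  )
  simulate_beats(sinus_params(tsys = lf$tsys, th = lf$th, mp = lf$mp, m = lf$m),
                 mod, duration_s)
}

#' Inject artifact beats into a series
#'
#' Deterministic (seeded) generator counterpart of real-world beat
#' annotation errors, used to exercise artifact cleaning against known
#' ground truth. Two kinds are supported:
#' \describe{
#'   \item{ectopic_short_long}{a premature-contraction signature: a beat
#'     pair's periods are replaced by 0.6x and 1.4x their local mean, so the
#'     pair's total duration is conserved;}
#'   \item{missed_beat}{a detection dropout: two adjacent periods are merged
#'     into one beat, reducing the beat count by one per event.}
#' }
#' Onset times are rebuilt by cumulative summation so timing stays
#' consistent with the periods. Affected beats are flagged `valid = FALSE`
#' as ground truth.
#'
#' @param b A [beat_series()].
#' @param fraction Proportion of beats to perturb, in `[0, 0.05]` (real
#'   recordings of the kind this emulates have well under 1% artifacts).
#' @param kind Artifact kind, see Details.
#' @param seed Integer seed; the same seed always yields the same output.
#'
#' @return A [beat_series()] with ground-truth `valid` flags.
#' @export
inject_artifacts <- function(b, fraction,
                             kind = c("ectopic_short_long", "missed_beat"),
                             seed = 0) {
  b <- as_beat_series(b)
  kind <- match.arg(kind)
  if (fraction < 0 || fraction > 0.05) {
    rlang::abort("fraction must lie in [0, 0.05]")
  }
  n <- nrow(b)
  n_events <- round(fraction * n)
  if (n_events == 0) return(b)

  # seeded, side-effect-free site selection: pairs (i, i+1) away from edges,
  # no two events sharing or abutting a beat
  sites <- withr::with_seed(seed, {
    candidates <- seq(2L, n - 2L)
    picked <- integer(0)
    while (length(picked) < n_events && length(candidates) > 0) {
      i <- if (length(candidates) == 1L) candidates else sample(candidates, 1L)
      picked <- c(picked, i)
      candidates <- setdiff(candidates, (i - 2L):(i + 2L))
    }
    sort(picked)
  })
  if (length(sites) < n_events) {
    rlang::abort("series too short to place the requested artifact events")
  }

  rr <- b$rr_ms
  valid <- b$valid
  if (kind == "ectopic_short_long") {
    for (i in sites) {
      local_hp <- mean(rr[c(i, i + 1L)])
      rr[i] <- 0.6 * local_hp
      rr[i + 1L] <- 1.4 * local_hp
      valid[c(i, i + 1L)] <- FALSE
    }
    keep <- rep(TRUE, n)
  } else {
    keep <- rep(TRUE, n)
    for (i in sites) {
      rr[i] <- rr[i] + rr[i + 1L]
      keep[i + 1L] <- FALSE
      valid[i] <- FALSE
    }
  }
  rr <- rr[keep]
  valid <- valid[keep]
  times <- b$time_s[1] + c(0, cumsum(rr[-length(rr)]) / 1000)
  meta <- attr(b, "meta") %||% list()
  meta$artifacts <- list(kind = kind, fraction = fraction, seed = seed,
                         n_events = n_events)
  beat_series(times, rr, valid, meta = meta)
}

#' @export
print.beat_series <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<beat_series: %d beats, %.1f s, mean RR %.1f ms%s>\n",
              nrow(x), diff(range(x$time_s)), mean(x$rr_ms),
              if (!all(x$valid)) sprintf(", %d flagged", sum(!x$valid)) else ""))
  NextMethod()
}
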