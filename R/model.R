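#' Sinoatrial node parameter sets
#'
#' Builds a tibble of sinoatrial action-potential parameter sets, one row per
#' parameterization. Four constants describe a pacemaker cell: `tsys`, the
#' duration from the start of Phase 0 to the end of Phase 3 (systole, ms);
#' `th`, the threshold membrane potential that triggers a new action potential
#' (mV); `mp`, the membrane potential at the end of Phase 3 repolarization
#' (mV); and `m`, the slope of the linear Phase 4 diastolic depolarization
#' (mV/ms). Parasympathetic activity hyperpolarizes `mp` and lowers `m`;
#' sympathetic activity raises `m`. `th` is held fixed by assumption: it is
#' configurable here but modulating it lies outside the framework.
#'
#' Optional fluctuation half-amplitudes describe autonomic modulation around
#' the mean: `dmp` (mV) for the membrane potential and `dm` (mV/ms) for the
#' Phase 4 slope.
#'
#' @param tsys Systole duration in ms (default 300).
#' @param th Threshold potential in mV (default -40).
#' @param mp End-of-repolarization membrane potential in mV (default -60).
#' @param m Phase 4 depolarization slope in mV/ms (default 0.036).
#' @param dmp Half-amplitude of `mp` fluctuation in mV (default 0).
#' @param dm Half-amplitude of `m` fluctuation in mV/ms (default 0).
#'
#' @return A tibble with columns `tsys`, `th`, `mp`, `m`, `dmp`, `dm`;
#'   arguments are recycled to a common length.
#' @examples
#' sinus_params()                      # resting (control) cell
#' sinus_params(mp = -55, m = 0.046)   # sympathetically driven cell
#' @export
sinus_params <- function(tsys = 300, th = -40, mp = -60, m = 0.036,
                         dmp = 0, dm = 0) {
  p <- tibble::tibble(tsys = tsys, th = th, mp = mp, m = m, dmp = dmp, dm = dm)
  validate_sinus_params(p)
  p
}

validate_sinus_params <- function(p) {
  need <- c("tsys", "th", "mp", "m")
  missing <- setdiff(need, names(p))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing parameter column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (any(p$tsys < 0)) rlang::abort("tsys must be >= 0")
  if (any(p$m <= 0)) {
    rlang::abort("non-firing parameterization: Phase 4 slope m must be > 0")
  }
  if (any(p$mp >= p$th)) {
    rlang::abort(
      "non-firing parameterization: mp must lie strictly below threshold th")
  }
  if (!is.null(p$dmp) && any(p$dmp < 0)) rlang::abort("dmp must be >= 0")
  if (!is.null(p$dm) && any(p$dm < 0)) rlang::abort("dm must be >= 0")
  invisible(p)
}

validate_fluct <- function(p) {
  if (is.null(p$dmp) || is.null(p$dm)) {
    rlang::abort("fluctuation columns dmp and dm are required")
  }
  if (any(p$m - p$dm <= 0)) {
    rlang::abort("dm too large: modulated slope m - dm must stay > 0")
  }
  if (any(p$mp + p$dmp >= p$th)) {
    rlang::abort("dmp too large: mp + dmp must stay strictly below th")
  }
  invisible(p)
}

#' Heart period and heart rate of a sinoatrial parameter set
#'
#' The cell fires when the Phase 4 ramp, starting at `mp` and rising with
#' slope `m`, reaches threshold `th`; the diastolic interval is therefore
#' `(th - mp) / m` and the heart period is
#' \deqn{HP = t_{sys} + (th - MP)/m \quad \textrm{(ms)},}
#' with heart rate \eqn{HR = 60000 / HP} (bpm).
#'
#' @param params A data frame of parameter sets as built by [sinus_params()].
#'
#' @return The input tibble with an added `hp_ms` (or `hr_bpm`) column.
#' @examples
#' heart_rate(sinus_params())  # ~70 bpm at rest
#' @export
heart_period <- function(params) {
  params <- tibble::as_tibble(params)
  validate_sinus_params(params)
  dplyr::mutate(params, hp_ms = .data$tsys + (.data$th - .data$mp) / .data$m)
}

#' @rdname heart_period
#' @export
heart_rate <- function(params) {
  hp <- heart_period(params)
  dplyr::mutate(hp, hr_bpm = 60000 / .data$hp_ms, hp_ms = NULL)
}

#' Peak-to-trough variability of heart period and heart rate
#'
#' Under autonomic modulation the membrane potential swings over
#' `mp +/- dmp` and the Phase 4 slope over `m +/- dm`. The extremes of the
#' heart period occur at the two opposed parameter excursions, giving the
#' peak-to-trough heart-period variability
#' \deqn{\Delta HP = \left| \frac{th - MP - \Delta MP}{m + \Delta m}
#'   - \frac{th - MP + \Delta MP}{m - \Delta m} \right|}
#' and correspondingly for heart rate with each excursion passed through
#' \eqn{60000/(t_{sys} + \cdot)}. The magnitude (highest minus lowest value)
#' is returned; the signed form of the expression is negative for typical
#' resting parameters because the first term is the shortest period.
#' `tsys` cancels in \eqn{\Delta HP} but not in \eqn{\Delta HR}.
#'
#' @param params A data frame with columns `tsys`, `th`, `mp`, `m`, `dmp`,
#'   `dm` (see [sinus_params()]).
#'
#' @return The input tibble with an added `dhp_ms` (or `dhr_bpm`) column.
#' @examples
#' # resting cell with LF-scale modulation of both mp and m
#' hp_variability(sinus_params(dmp = 2, dm = 0.002))
#' @export
hp_variability <- function(params) {
  params <- tibble::as_tibble(params)
  validate_sinus_params(params)
  validate_fluct(params)
  dplyr::mutate(
    params,
    dhp_ms = abs((.data$th - .data$mp - .data$dmp) / (.data$m + .data$dm) -
                 (.data$th - .data$mp + .data$dmp) / (.data$m - .data$dm))
  )
}

#' @rdname hp_variability
#' @export
hr_variability <- function(params) {
  params <- tibble::as_tibble(params)
  validate_sinus_params(params)
  validate_fluct(params)
  dplyr::mutate(
    params,
    dhr_bpm = abs(
      60000 / (.data$tsys + (.data$th - .data$mp - .data$dmp) / (.data$m + .data$dm)) -
      60000 / (.data$tsys + (.data$th - .data$mp + .data$dmp) / (.data$m - .data$dm)))
  )
}

#' All four model predictions at once
#'
#' Convenience wrapper adding `hp_ms`, `hr_bpm`, `dhp_ms` and `dhr_bpm` for
#' each parameter row. The `+/-` half-deviations quoted alongside
#' peak-to-trough magnitudes are `dhp_ms / 2` and `dhr_bpm / 2`.
#'
#' @inheritParams hp_variability
#' @return The input tibble with the four prediction columns appended.
#' @export
predict_variability <- function(params) {
  params |>
    heart_period() |>
    dplyr::mutate(hr_bpm = 60000 / .data$hp_ms) |>
    hp_variability() |>
    hr_variability()
}

#' Autonomic scenario presets
#'
#' The three canonical autonomic states of the framework, each with an LF
#' and an HF fluctuation row (six rows in total):
#' \describe{
#'   \item{control}{resting tone: `mp = -60` mV, `m = 0.036` mV/ms,
#'     LF `dm = 0.002` mV/ms.}
#'   \item{high_sna_low_pna}{raised sympathetic / withdrawn parasympathetic
#'     tone: `mp = -57` mV, `m = 0.040` mV/ms, LF `dm = 0.003` mV/ms.}
#'   \item{low_sna_high_pna}{withdrawn sympathetic / raised parasympathetic
#'     tone: `mp = -63` mV, `m = 0.032` mV/ms, LF `dm = 0.001` mV/ms.}
#' }
#' All scenarios share `tsys = 300` ms, `th = -40` mV and `dmp = 2` mV. HF
#' rows force `dm = 0`: the cAMP turnover behind slope fluctuations is too
#' sluggish to follow high-frequency (respiratory) drive, so HF variability
#' is carried by membrane-potential fluctuation alone.
#'
#' @return A tibble with columns `scenario`, `band` ("lf"/"hf"), `tsys`,
#'   `th`, `mp`, `m`, `dmp`, `dm`.
#' @examples
#' scenario_presets() |> predict_variability()
#' @export
scenario_presets <- function() {
  base <- tibble::tibble(
    scenario = c("control", "high_sna_low_pna", "low_sna_high_pna"),
    mp = c(-60, -57, -63),
    m = c(0.036, 0.040, 0.032),
    dm_lf = c(0.002, 0.003, 0.001)
  )
  base |>
    tidyr::crossing(band = c("lf", "hf")) |>
    dplyr::mutate(
      tsys = 300, th = -40, dmp = 2,
      dm = dplyr::if_else(.data$band == "lf", .data$dm_lf, 0),
      dm_lf = NULL
    ) |>
    dplyr::select("scenario", "band", "tsys", "th", "mp", "m", "dmp", "dm") |>
    dplyr::arrange(.data$scenario, dplyr::desc(.data$band))
}

scenario_names <- function() c("control", "high_sna_low_pna", "low_sna_high_pna")

#' Variability sweeps over fluctuation amplitude
#'
#' `sweep_dm()` evaluates the LF predictions over a grid of slope-fluctuation
#' half-amplitudes `dm` with the membrane-potential fluctuation fixed
#' (`dmp = 2` mV by default); `sweep_dmp()` evaluates the HF predictions over
#' a grid of `dmp` values with `dm = 0`, where the heart-period response is
#' exactly linear: \eqn{\Delta HP = 2\,\Delta MP / m}.
#'
#' @param params A one-row data frame of base parameters ([sinus_params()]).
#' @param dm_grid,dmp_grid Numeric grids of fluctuation half-amplitudes
#'   (mV/ms and mV respectively).
#' @param dmp Fixed membrane-potential fluctuation for `sweep_dm()`, mV.
#'
#' @return A tibble of class `hrv_sweep` with the grid column (`dm` or
#'   `dmp`), `dhp_ms` and `dhr_bpm`.
#' @examples
#' sweep_dm(sinus_params(), dm_grid = seq(0, 0.005, by = 0.001))
#' @export
sweep_dm <- function(params, dm_grid, dmp = 2) {
  params <- tibble::as_tibble(params)
  stopifnot(nrow(params) == 1)
  if (any(dm_grid >= params$m)) {
    rlang::abort("dm grid point >= m: modulated slope would be non-positive")
  }
  grid <- params |>
    dplyr::select("tsys", "th", "mp", "m") |>
    tidyr::crossing(dm = dm_grid) |>
    dplyr::mutate(dmp = dmp) |>
    predict_variability() |>
    dplyr::select("dm", "dhp_ms", "dhr_bpm") |>
    dplyr::arrange(.data$dm)
  structure(grid, class = c("hrv_sweep", class(grid)), vary = "dm")
}

#' @rdname sweep_dm
#' @export
sweep_dmp <- function(params, dmp_grid) {
  params <- tibble::as_tibble(params)
  stopifnot(nrow(params) == 1)
  if (any(params$mp + dmp_grid >= params$th)) {
    rlang::abort("dmp grid point too large: mp + dmp must stay below th")
  }
  grid <- params |>
    dplyr::select("tsys", "th", "mp", "m") |>
    tidyr::crossing(dmp = dmp_grid) |>
    dplyr::mutate(dm = 0) |>
    predict_variability() |>
    dplyr::select("dmp", "dhp_ms", "dhr_bpm") |>
    dplyr::arrange(.data$dmp)
  structure(grid, class = c("hrv_sweep", class(grid)), vary = "dmp")
}

#' Stylized sinoatrial action-potential waveform
#'
#' Renders the model's membrane-potential trajectory for plotting: per beat,
#' a linear Phase 4 ramp from `mp` to `th` with slope `m` (duration
#' `(th - mp) / m` ms), followed by a stylized systolic segment of duration
#' `tsys` (fast upstroke to +20 mV, sagging plateau, repolarization back to
#' `mp`). Only the segment durations are mechanistically meaningful; the
#' systolic shape is cosmetic. Consecutive beat onsets are spaced by the
#' heart period.
#'
#' @param params A one-row data frame of parameters ([sinus_params()]).
#' @param n_beats Number of beats to render (>= 1).
#' @param dt Sample spacing in ms.
#'
#' @return A tibble of class `ap_waveform` with columns `time_ms`, `vm_mv`,
#'   `beat`, `phase` ("diastole"/"systole").
#' @export
ap_waveform <- function(params, n_beats = 3, dt = 1) {
  params <- tibble::as_tibble(params)
  stopifnot(nrow(params) == 1, n_beats >= 1, dt > 0)
  validate_sinus_params(params)
  hp <- heart_period(params)$hp_ms
  ramp_dur <- (params$th - params$mp) / params$m

  one_beat <- function(beat) {
    t <- seq(0, hp, by = dt)
    t <- t[t < hp]  # next beat owns the onset sample
    if (max(t) < ramp_dur) t <- sort(c(t, ramp_dur))
    if (!any(t == ramp_dur)) t <- sort(c(t, ramp_dur))  # exact threshold sample
    in_ramp <- t <= ramp_dur
    vm <- numeric(length(t))
    vm[in_ramp] <- params$mp + params$m * t[in_ramp]
    # systole: upstroke 5% of tsys to +20 mV, plateau sag to 0 mV over 40%,
    # Phase 3 repolarization back to mp over the remainder
    ts <- (t[!in_ramp] - ramp_dur) / params$tsys
    vm[!in_ramp] <- ifelse(
      ts < 0.05, params$th + (20 - params$th) * ts / 0.05,
      ifelse(ts < 0.45, 20 - 20 * (ts - 0.05) / 0.40,
             0 + (params$mp - 0) * (ts - 0.45) / 0.55))
    tibble::tibble(
      time_ms = (beat - 1) * hp + t,
      vm_mv = vm,
      beat = beat,
      phase = dplyr::if_else(in_ramp, "diastole", "systole")
    )
  }
  wf <- purrr::map_dfr(seq_len(n_beats), one_beat)
  structure(wf, class = c("ap_waveform", class(wf)),
            params = params, hp_ms = hp)
}

# round half away from zero, the convention used for printed predictions
round_half_out <- function(x) sign(x) * floor(abs(x) + 0.5)
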