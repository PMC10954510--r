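#' Detect and interpolate artifact beats
#'
#' Beats whose period deviates from a running median (default window 11
#' beats) by more than `rel_threshold` (a proportion of the local median) are
#' treated as artifacts — ectopic beats, missed detections — and replaced by
#' linear interpolation between the nearest surrounding normal beats, the
#' usual correction applied to RR tachograms before HRV analysis. The beat
#' count is unchanged; replaced beats are flagged valid in the output (their
#' values are now usable) and listed in the attached cleaning report. If
#' more than 5% of beats need replacement a quality warning is raised:
#' that is far beyond what interpolation can credibly repair.
#'
#' @param b A [beat_series()] or data frame coercible to one.
#' @param rel_threshold Relative deviation triggering replacement,
#'   in (0, 1); default 0.3.
#' @param window Running-median window in beats (odd; default 11).
#'
#' @return A [beat_series()] with attribute `"cleaning"` (a list with
#'   `replaced` indices, `pct_interpolated`, `quality_flag`); retrieve it
#'   with [cleaning_report()].
#' @examples
#' b <- simulate_beats(sinus_params(), duration_s = 60)
#' cleaning_report(clean_beats(b))$pct_interpolated  # 0 on a clean series
#' @export
clean_beats <- function(b, rel_threshold = 0.3, window = 11) {
  b <- as_beat_series(b)
  if (rel_threshold <= 0 || rel_threshold >= 1) {
    rlang::abort("rel_threshold must lie in (0, 1)")
  }
  rr <- b$rr_ms
  n <- length(rr)
  if (n < 2) rlang::abort("cannot clean a series of fewer than 2 beats")
  k <- min(window, if (n %% 2 == 1) n else n - 1)
  med <- stats::runmed(rr, k, endrule = "median")
  bad <- abs(rr - med) / med > rel_threshold
  if (any(bad) && !all(bad)) {
    good_idx <- which(!bad)
    rr[bad] <- stats::approx(x = b$time_s[good_idx], y = rr[good_idx],
                             xout = b$time_s[bad], rule = 2)$y
  }
  pct <- mean(bad)
  if (pct > 0.05) {
    rlang::warn(sprintf(
      "poor record quality: %.1f%% of beats replaced by interpolation",
      100 * pct), class = "hrvmech_quality_warning")
  }
  out <- beat_series(b$time_s, rr, valid = TRUE, meta = attr(b, "meta"))
  attr(out, "cleaning") <- list(replaced = which(bad),
                                pct_interpolated = pct,
                                quality_flag = pct > 0.05)
  out
}

#' @rdname clean_beats
#' @param x A cleaned beat series.
#' @export
cleaning_report <- function(x) attr(x, "cleaning")

#' Split a beat series into overlapping analysis segments
#'
#' Divides the record into windows of `window_s` seconds starting every
#' `window_s * (1 - overlap)` seconds from the first beat; each segment
#' holds the beats whose onset lies in `[start, start + window_s)`. A
#' trailing remainder shorter than a full window is dropped, except that the
#' final full-width window is kept when the record falls short of it by less
#' than one median beat interval (a record that nominally spans 30 min ends
#' mid-beat). A record shorter than one window yields a single whole-record
#' segment, flagged in the result.
#'
#' @param b A [beat_series()].
#' @param window_s Segment length in seconds (default 300 = 5 min).
#' @param overlap Fractional overlap between consecutive segments
#'   (default 0.5).
#'
#' @return A tibble with columns `segment`, `start_s`, `end_s`, `n_beats`
#'   and a `beats` list-column of beat-series tibbles; attribute
#'   `"short_record"` is TRUE for the single-segment fallback.
#' @examples
#' b <- simulate_beats(sinus_params(), duration_s = 1800)
#' nrow(segment_beats(b))  # 11 five-minute segments at 50% overlap
#' @export
segment_beats <- function(b, window_s = 300, overlap = 0.5) {
  b <- as_beat_series(b)
  stopifnot(window_s > 0, overlap >= 0, overlap < 1)
  t0 <- b$time_s[1]
  span <- b$time_s[nrow(b)] - t0
  tol <- stats::median(b$rr_ms) / 1000
  short <- span + tol < window_s
  if (short) {
    starts <- t0
    window_s_eff <- span + tol
  } else {
    hop <- window_s * (1 - overlap)
    n_seg <- floor((span + tol - window_s) / hop) + 1
    starts <- t0 + hop * (seq_len(n_seg) - 1)
    window_s_eff <- window_s
  }
  seg <- tibble::tibble(
    segment = seq_along(starts),
    start_s = starts,
    end_s = starts + window_s_eff
  ) |>
    dplyr::mutate(beats = purrr::map2(.data$start_s, .data$end_s, function(s, e) {
      dplyr::filter(tibble::as_tibble(b), .data$time_s >= s, .data$time_s < e)
    }),
    n_beats = purrr::map_int(.data$beats, nrow))
  structure(seg, short_record = short)
}

#' Time-domain HRV statistics of a segment
#'
#' `sdnn()` is the standard deviation of the normal-beat heart periods
#' (population convention, divide by n — at ~300 beats per 5-min segment
#' the sample-convention difference is negligible; set `population = FALSE`
#' for the n-1 convention). `rmssd()` is the root mean square of successive
#' differences, taken only between adjacent normal beats; it weights
#' beat-to-beat changes and hence respiratory-frequency variability.
#'
#' @param seg A beat series or segment data frame with `rr_ms` and `valid`.
#' @param population Use the population (n) SD convention (default TRUE).
#'
#' @return Length-one numeric, in ms.
#' @examples
#' sdnn(beat_series(c(0, .79, 1.59), c(790, 800, 810)))   # 8.165 ms
#' rmssd(beat_series(c(0, .8, 1.61), c(800, 810, 790)))   # 15.81 ms
#' @export
sdnn <- function(seg, population = TRUE) {
  rr <- seg$rr_ms[seg$valid %||% rep(TRUE, nrow(seg))]
  if (length(rr) < 2) rlang::abort("sdnn needs at least 2 valid beats")
  if (population) sqrt(mean((rr - mean(rr))^2)) else stats::sd(rr)
}

#' @rdname sdnn
#' @export
rmssd <- function(seg) {
  valid <- seg$valid %||% rep(TRUE, nrow(seg))
  if (sum(valid) < 2) rlang::abort("rmssd needs at least 2 valid beats")
  adjacent <- valid[-length(valid)] & valid[-1]
  d <- diff(seg$rr_ms)[adjacent]
  if (length(d) == 0) rlang::abort("no adjacent pair of valid beats")
  sqrt(mean(d^2))
}

#' Segment-averaged time-domain HRV summary
#'
#' The full time-domain chain: clean the series ([clean_beats()]), divide it
#' into 50%-overlapping 5-min segments ([segment_beats()]), compute SDNN and
#' RMSSD per segment, and average across segments. The segment averages are
#' the record-level statistics.
#'
#' @param b A [beat_series()].
#' @param window_s,overlap Segmentation parameters, see [segment_beats()].
#' @param rel_threshold,window Cleaning parameters, see [clean_beats()].
#' @param clean Set FALSE to skip artifact cleaning.
#'
#' @return An object of class `hrv_time`: a list with `sdnn_ms`, `rmssd_ms`,
#'   `n_segments`, `pct_interpolated`, `short_record` and a `segments`
#'   tibble of per-segment values. [tidy()] returns the per-segment table,
#'   [glance()] the one-row summary.
#' @examples
#' b <- simulate_beats(sinus_params(),
#'                     modulation_spec(mp_hf_amp = 2), duration_s = 600)
#' glance(hrv_time(b))
#' @export
hrv_time <- function(b, window_s = 300, overlap = 0.5,
                     rel_threshold = 0.3, window = 11, clean = TRUE) {
  b <- as_beat_series(b)
  pct <- 0
  if (clean) {
    b <- clean_beats(b, rel_threshold = rel_threshold, window = window)
    pct <- cleaning_report(b)$pct_interpolated
  }
  seg <- segment_beats(b, window_s = window_s, overlap = overlap)
  per_seg <- seg |>
    dplyr::mutate(sdnn_ms = purrr::map_dbl(.data$beats, sdnn),
                  rmssd_ms = purrr::map_dbl(.data$beats, rmssd)) |>
    dplyr::select("segment", "start_s", "end_s", "n_beats",
                  "sdnn_ms", "rmssd_ms")
  structure(
    list(sdnn_ms = mean(per_seg$sdnn_ms),
         rmssd_ms = mean(per_seg$rmssd_ms),
         n_segments = nrow(per_seg),
         pct_interpolated = pct,
         short_record = isTRUE(attr(seg, "short_record")),
         segments = per_seg),
    class = "hrv_time")
}

#' @export
print.hrv_time <- function(x, ...) {
  cat(sprintf(
    "Time-domain HRV (%d segment%s%s)\n  SDNN  %.2f ms\n  RMSSD %.2f ms\n  %.2f%% of beats interpolated\n",
    x$n_segments, if (x$n_segments == 1) "" else "s",
    if (x$short_record) ", short record" else "",
    x$sdnn_ms, x$rmssd_ms, 100 * x$pct_interpolated))
  invisible(x)
}

#' @export
tidy.hrv_time <- function(x, ...) x$segments

#' @export
glance.hrv_time <- function(x, ...) {
  tibble::tibble(sdnn_ms = x$sdnn_ms, rmssd_ms = x$rmssd_ms,
                 n_segments = x$n_segments,
                 pct_interpolated = x$pct_interpolated)
}
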