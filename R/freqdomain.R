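#' Convert between heart period and heart rate
#'
#' Element-wise `60000 / x`. The same map converts heart period (ms) to
#' heart rate (bpm) and back, so the function is its own inverse; the two
#' series representations analyzed by the pipeline are the identical beat
#' data expressed in either unit.
#'
#' @param x Positive numeric vector (ms or bpm).
#' @return Numeric vector in the other representation.
#' @examples
#' hp_to_hr(600)           # 100 bpm
#' hp_to_hr(hp_to_hr(855.56))  # involution
#' @export
hp_to_hr <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort("values must be positive and finite to convert")
  }
  60000 / x
}

#' @rdname hp_to_hr
#' @export
hr_to_hp <- hp_to_hr

#' Resample a beat series onto a uniform grid
#'
#' Beat series are unevenly sampled (one value per beat), so spectra require
#' an evenly sampled tachogram: a cubic spline is fitted through the
#' `(onset time, value)` knots and evaluated on a uniform grid spanning the
#' record (no extrapolation beyond the first/last beat). The default 12 Hz
#' grid comfortably oversamples the <= 0.4 Hz band of interest. The value at
#' each knot is the beat's heart period anchored at that beat's onset, or
#' its heart-rate equivalent via [hp_to_hr()].
#'
#' @param b A [beat_series()].
#' @param fs Sampling rate in Hz (default 12).
#' @param representation `"hp"` for heart period (ms) or `"hr"` for heart
#'   rate (bpm).
#'
#' @return A tibble of class `resampled_series` with columns `time_s`,
#'   `value`; attributes `fs` and `representation`.
#' @export
resample_even <- function(b, fs = 12, representation = c("hp", "hr")) {
  b <- as_beat_series(b)
  representation <- match.arg(representation)
  if (nrow(b) < 4) rlang::abort("resampling needs at least 4 beats")
  y <- if (representation == "hr") hp_to_hr(b$rr_ms) else b$rr_ms
  f <- stats::splinefun(b$time_s, y, method = "fmm")
  grid <- seq(b$time_s[1], b$time_s[nrow(b)], by = 1 / fs)
  out <- tibble::tibble(time_s = grid, value = f(grid))
  structure(out, class = c("resampled_series", class(out)),
            fs = fs, representation = representation)
}

taper_window <- function(n, taper) {
  switch(taper,
         hann = 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)),
         rectangular = rep(1, n),
         rlang::abort("unknown taper"))
}

#' Averaged overlapping-segment power spectrum
#'
#' Welch-style spectral estimate of an evenly resampled series: the series
#' is divided into overlapping segments (default 50% overlap, 2024 samples =
#' 168.7 s at 12 Hz), each segment is mean-removed and tapered (Hann by
#' default), its one-sided periodogram is computed with density scaling
#' `2 |FFT(w x)|^2 / (fs * sum(w^2))` so that the integral of the PSD over
#' frequency equals the taper-corrected segment variance, and the segment
#' periodograms are averaged. A series shorter than one segment is analyzed
#' as a single shortened segment and flagged.
#'
#' The default segment length is 2024 samples, not the power of two 2048;
#' the FFT handles arbitrary lengths and the length is configurable.
#'
#' @param s A `resampled_series` from [resample_even()].
#' @param seg_len Segment length in samples (default 2024).
#' @param overlap Fractional overlap (default 0.5).
#' @param taper `"hann"` (default) or `"rectangular"`.
#'
#' @return A tibble of class `hrv_psd` with columns `freq_hz` and `power`
#'   (series-units squared per Hz); attributes `fs`, `n_segments`,
#'   `representation`, `short_segment`.
#' @export
averaged_psd <- function(s, seg_len = 2024, overlap = 0.5,
                         taper = c("hann", "rectangular")) {
  taper <- match.arg(taper)
  stopifnot(seg_len > 1, overlap >= 0, overlap < 1)
  fs <- attr(s, "fs")
  if (is.null(fs)) rlang::abort("input must come from resample_even()")
  x <- s$value
  n <- length(x)
  short <- n < seg_len
  if (short) {
    starts <- 1L
    seg_len <- n
    rlang::warn("series shorter than one spectral segment; using one shortened segment",
                class = "hrvmech_short_segment")
  } else {
    hop <- max(1L, floor(seg_len * (1 - overlap)))
    starts <- seq(1L, n - seg_len + 1L, by = hop)
  }
  w <- taper_window(seg_len, taper)
  nf <- floor(seg_len / 2)
  acc <- numeric(nf)
  for (st in starts) {
    seg <- x[st:(st + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    p <- 2 * Mod(X[2:(nf + 1L)])^2 / (fs * sum(w^2))
    if (seg_len %% 2 == 0) p[nf] <- p[nf] / 2  # Nyquist bin is not doubled
    acc <- acc + p
  }
  out <- tibble::tibble(freq_hz = seq_len(nf) * fs / seg_len,
                        power = acc / length(starts))
  structure(out, class = c("hrv_psd", class(out)),
            fs = fs, n_segments = length(starts),
            representation = attr(s, "representation"),
            short_segment = short)
}

#' Spectral band power
#'
#' Area under the PSD curve over the band `[f_lo, f_hi)`: a trapezoidal
#' integral over the frequency bins inside the band, with the spectrum
#' linearly interpolated at the exact band edges. The canonical bands are
#' LF `[0.04, 0.15)` Hz and HF `[0.15, 0.40)` Hz; because the shared
#' 0.15 Hz edge has zero width in the integral, abutting bands tile the
#' axis without double counting and band powers are additive over disjoint
#' bands.
#'
#' @param psd An `hrv_psd` tibble from [averaged_psd()] (columns `freq_hz`,
#'   `power`).
#' @param f_lo,f_hi Band edges in Hz, `f_lo < f_hi`.
#'
#' @return Band power in series-units squared.
#' @examples
#' \dontrun{band_power(psd, 0.04, 0.15)  # LF power}
#' @export
band_power <- function(psd, f_lo, f_hi) {
  if (f_lo >= f_hi) rlang::abort("inverted band: f_lo must be < f_hi")
  f <- psd$freq_hz
  p <- psd$power
  lo <- max(f_lo, f[1])
  hi <- min(f_hi, f[length(f)])
  if (lo >= hi) return(0)
  inner <- f > lo & f < hi
  fi <- c(lo, f[inner], hi)
  pi <- c(stats::approx(f, p, lo)$y, p[inner], stats::approx(f, p, hi)$y)
  sum(diff(fi) * (pi[-1] + pi[-length(pi)]) / 2)
}

#' Frequency-domain HRV summary from both series representations
#'
#' The complete spectral chain: clean the beat series, resample both the
#' heart-period (ms) and the heart-rate (bpm) representation of the same
#' beats onto a uniform grid, estimate each averaged spectrum, and integrate
#' the LF `[0.04, 0.15)` Hz and HF `[0.15, 0.40)` Hz bands. Three LF/HF
#' ratios are reported: within the heart-period spectrum (`ratio_hp`),
#' within the heart-rate spectrum (`ratio_hr`), and the cross-representation
#' ratio `ratio_cross = lf_hr / hf_hp` — LF power taken from the
#' representation in which sympathetic modulation is monotone (heart rate)
#' over HF power from the representation in which parasympathetic
#' modulation is monotone (heart period), proposed as the more sensitive
#' autonomic-balance index.
#'
#' @param b A [beat_series()].
#' @param fs Resampling rate, Hz.
#' @param seg_len,overlap,taper Spectral parameters, see [averaged_psd()].
#' @param lf,hf Numeric length-2 band edges in Hz.
#' @param rel_threshold,window Cleaning parameters, see [clean_beats()].
#' @param clean Set FALSE to skip artifact cleaning.
#'
#' @return An object of class `hrv_spectral`: a list with band powers
#'   `lf_hp`, `hf_hp` (ms^2), `lf_hr`, `hf_hr` (bpm^2), the three ratios
#'   (NA when a denominator is 0), `n_segments`, `pct_interpolated`, and
#'   the two `hrv_psd` tibbles (`psd_hp`, `psd_hr`). [tidy()] returns the
#'   band-power table, [glance()] a one-row summary.
#' @examples
#' b <- simulate_beats(sinus_params(),
#'                     modulation_spec(mp_lf_amp = 2, m_lf_amp = 0.002),
#'                     duration_s = 600)
#' glance(hrv_spectral(b))
#' @export
hrv_spectral <- function(b, fs = 12, seg_len = 2024, overlap = 0.5,
                         taper = c("hann", "rectangular"),
                         lf = c(0.04, 0.15), hf = c(0.15, 0.40),
                         rel_threshold = 0.3, window = 11, clean = TRUE) {
  b <- as_beat_series(b)
  taper <- match.arg(taper)
  pct <- 0
  if (clean) {
    b <- clean_beats(b, rel_threshold = rel_threshold, window = window)
    pct <- cleaning_report(b)$pct_interpolated
  }
  psd_hp <- averaged_psd(resample_even(b, fs = fs, representation = "hp"),
                         seg_len = seg_len, overlap = overlap, taper = taper)
  psd_hr <- averaged_psd(resample_even(b, fs = fs, representation = "hr"),
                         seg_len = seg_len, overlap = overlap, taper = taper)
  lf_hp <- band_power(psd_hp, lf[1], lf[2])
  hf_hp <- band_power(psd_hp, hf[1], hf[2])
  lf_hr <- band_power(psd_hr, lf[1], lf[2])
  hf_hr <- band_power(psd_hr, hf[1], hf[2])
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(lf_hp = lf_hp, hf_hp = hf_hp, lf_hr = lf_hr, hf_hr = hf_hr,
         ratio_hp = ratio(lf_hp, hf_hp),
         ratio_hr = ratio(lf_hr, hf_hr),
         ratio_cross = ratio(lf_hr, hf_hp),
         n_segments = attr(psd_hp, "n_segments"),
         pct_interpolated = pct,
         psd_hp = psd_hp, psd_hr = psd_hr),
    class = "hrv_spectral")
}

#' @export
print.hrv_spectral <- function(x, ...) {
  cat(sprintf(paste0(
    "Frequency-domain HRV (%d spectral segment%s)\n",
    "  LF_HP %8.1f ms^2   HF_HP %8.1f ms^2   LF/HF (HP) %s\n",
    "  LF_HR %8.2f bpm^2  HF_HR %8.2f bpm^2  LF/HF (HR) %s\n",
    "  LF_HR/HF_HP (cross) %s\n"),
    x$n_segments, if (x$n_segments == 1) "" else "s",
    x$lf_hp, x$hf_hp, format_ratio(x$ratio_hp),
    x$lf_hr, x$hf_hr, format_ratio(x$ratio_hr),
    format_ratio(x$ratio_cross)))
  invisible(x)
}

format_ratio <- function(r) if (is.na(r)) "undefined" else sprintf("%.3f", r)

#' @export
tidy.hrv_spectral <- function(x, ...) {
  tibble::tibble(
    band = c("lf", "hf", "lf", "hf"),
    representation = c("hp", "hp", "hr", "hr"),
    power = c(x$lf_hp, x$hf_hp, x$lf_hr, x$hf_hr),
    units = c("ms^2", "ms^2", "bpm^2", "bpm^2")
  )
}

#' @export
glance.hrv_spectral <- function(x, ...) {
  tibble::tibble(lf_hp_ms2 = x$lf_hp, hf_hp_ms2 = x$hf_hp,
                 lf_hr_bpm2 = x$lf_hr, hf_hr_bpm2 = x$hf_hr,
                 ratio_hp = x$ratio_hp, ratio_hr = x$ratio_hr,
                 ratio_cross = x$ratio_cross,
                 n_segments = x$n_segments,
                 pct_interpolated = x$pct_interpolated)
}
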