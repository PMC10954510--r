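test_that("heart period and heart rate interconvert as an involution", {
  expect_equal(hp_to_hr(600), 100)
  expect_equal(hp_to_hr(855.56), 70.12949, tolerance = 1e-6)
  x <- c(600, 855.56, 1000)
  expect_equal(hp_to_hr(hp_to_hr(x)), x)
  expect_identical(hr_to_hp, hp_to_hr)
  expect_error(hp_to_hr(c(600, 0)), "positive")
  expect_error(hp_to_hr(-5), "positive")
})

test_that("spline resampling reproduces constants, lines and sinusoids", {
  const <- beat_series(seq(0, 8, by = 0.8), rep(800, 11))
  rs <- resample_even(const)
  expect_equal(unique(round(rs$value, 9)), 800)
  expect_equal(diff(rs$time_s), rep(1 / 12, nrow(rs) - 1), tolerance = 1e-12)

  ramp <- beat_series(seq(0, 8, by = 0.8), seq(700, 900, length.out = 11))
  rr <- resample_even(ramp)
  expect_lt(max(abs(rr$value - (700 + 25 * rr$time_s))), 1e-9)

  sine <- sinusoid_beats(120, function(t) 800 + 50 * sin(2 * pi * 0.1 * t))
  rs2 <- resample_even(sine)
  analytic <- 800 + 50 * sin(2 * pi * 0.1 * rs2$time_s)
  rel_rms <- sqrt(mean((rs2$value - analytic)^2)) / sqrt(mean(analytic^2))
  expect_lt(rel_rms, 0.01)

  expect_error(resample_even(beat_series(c(0, 0.8, 1.6), rep(800, 3))),
               "4 beats")
  hr <- resample_even(const, representation = "hr")
  expect_equal(unique(round(hr$value, 9)), 75)
})

test_that("the averaged spectrum conserves variance (Parseval)", {
  set.seed(11)
  n <- 6000
  rr <- 800 + stats::rnorm(n, sd = 30)
  b <- beat_series(seq(0, by = 1 / 12, length.out = n), rr)
  rs <- resample_even(b)  # knots coincide with the grid
  psd <- averaged_psd(rs, seg_len = 2024)
  total <- band_power(psd, 0, 6.0001)
  expect_equal(total, stats::var(rr), tolerance = 0.05)
  # rectangular taper, one segment: same conservation
  psd_r <- averaged_psd(rs, seg_len = n, taper = "rectangular")
  expect_equal(band_power(psd_r, 0, 6.0001), stats::var(rr), tolerance = 0.05)
})

test_that("sinusoids place their variance (A^2/2) in the correct band", {
  t <- seq(0, 700, by = 1 / 12)
  mk <- function(freq, amp) {
    b <- beat_series(t, 800 + amp * sin(2 * pi * freq * t))
    averaged_psd(resample_even(b))
  }
  lf_psd <- mk(0.1, 10)
  expect_equal(band_power(lf_psd, 0.04, 0.15), 50, tolerance = 0.05)
  expect_lt(band_power(lf_psd, 0.15, 0.40), 0.05 * 50)
  hf_psd <- mk(0.25, 10)
  expect_equal(band_power(hf_psd, 0.15, 0.40), 50, tolerance = 0.05)
  expect_lt(band_power(hf_psd, 0.04, 0.15), 0.05 * 50)
})

test_that("a constant series has an all-zero spectrum", {
  b <- beat_series(seq(0, 300, by = 0.8), rep(800, 376))
  psd <- averaged_psd(resample_even(b))
  expect_true(all(psd$power < 1e-18))
})

test_that("band powers are additive and bounded by total power", {
  set.seed(3)
  rr <- 800 + stats::rnorm(4096, sd = 20)
  rs <- resample_even(beat_series(seq(0, by = 1 / 12, length.out = 4096), rr))
  psd <- averaged_psd(rs)
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15, 0.40)
  both <- band_power(psd, 0.04, 0.40)
  expect_equal(lf + hf, both, tolerance = 1e-6)
  expect_lte(both, band_power(psd, 0, 6.001))
  expect_error(band_power(psd, 0.4, 0.15), "inverted")
})

test_that("short series fall back to a single shortened spectral segment", {
  b <- simulate_beats(control_params(), lf_only_mod(), duration_s = 100)
  rs <- resample_even(b)
  expect_warning(psd <- averaged_psd(rs), class = "hrvmech_short_segment")
  expect_equal(attr(psd, "n_segments"), 1)
  expect_true(attr(psd, "short_segment"))
})

test_that("the spectral summary fills both representations and all ratios", {
  b <- simulate_beats(control_params(), lf_only_mod(), duration_s = 600)
  s <- hrv_spectral(b)
  expect_s3_class(s, "hrv_spectral")
  expect_gt(s$ratio_hp, 10)   # LF-only drive
  expect_gt(s$ratio_hr, 10)
  expect_equal(s$ratio_cross, s$lf_hr / s$hf_hp)
  g <- glance(s)
  expect_named(g, c("lf_hp_ms2", "hf_hp_ms2", "lf_hr_bpm2", "hf_hr_bpm2",
                    "ratio_hp", "ratio_hr", "ratio_cross", "n_segments",
                    "pct_interpolated"))
  expect_equal(nrow(tidy(s)), 4)

  const <- beat_series(seq(0, 300, by = 0.8), rep(800, 376))
  sc <- hrv_spectral(const, clean = FALSE)
  expect_lt(sc$lf_hp + sc$hf_hp + sc$lf_hr + sc$hf_hr, 1e-12)
  expect_true(is.na(sc$ratio_hp) && is.na(sc$ratio_cross))
})

test_that("HP- and HR-derived spectra are near-proportional for small fluctuations", {
  mk <- function(amp) {
    b <- sinusoid_beats(600, function(t) 800 + amp * sin(2 * pi * 0.1 * t))
    s <- hrv_spectral(b, clean = FALSE)
    s$lf_hr / s$lf_hp
  }
  # for small fractional fluctuation the HR spectrum is a scaled HP
  # spectrum with factor (60000/hp^2)^2; the match degrades as amplitude grows
  small <- mk(20)
  large <- mk(200)
  k <- (60000 / 800^2)^2
  expect_equal(small, k, tolerance = 0.02)
  expect_gt(abs(large / k - 1), abs(small / k - 1))
})
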