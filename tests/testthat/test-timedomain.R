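const_series <- function(n = 10, rr = 800) {
  beat_series(seq(0, by = rr / 1000, length.out = n), rep(rr, n))
}

test_that("sdnn and rmssd reproduce hand-computed values", {
  expect_equal(sdnn(const_series()), 0)
  expect_equal(rmssd(const_series()), 0)

  alt <- beat_series(cumsum(rep(0.805, 10)), rep(c(800, 810), 5))
  expect_equal(sdnn(alt), 5)        # population SD of a two-point distribution
  expect_equal(rmssd(alt), 10)      # all successive differences are +/-10

  tri <- beat_series(c(0, 0.79, 1.59), c(790, 800, 810))
  expect_equal(sdnn(tri), 8.164966, tolerance = 1e-6)
  expect_equal(sdnn(tri, population = FALSE), 10)

  z <- beat_series(c(0, 0.8, 1.61), c(800, 810, 790))
  expect_equal(rmssd(z), sqrt((10^2 + 20^2) / 2), tolerance = 1e-9)

  expect_error(sdnn(const_series(1)), "2 valid beats")
  one_valid <- beat_series(c(0, 0.8, 1.6), c(800, 800, 800),
                           valid = c(TRUE, FALSE, FALSE))
  expect_error(rmssd(one_valid), "valid")
})

test_that("rmssd skips differences that straddle a non-normal beat", {
  b <- beat_series(cumsum(rep(0.8, 6)), c(800, 800, 1600, 800, 810, 800),
                   valid = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  # usable successive pairs: (1,2), (4,5), (5,6) -> diffs 0, 10, -10
  expect_equal(rmssd(b), sqrt(mean(c(0, 10, -10)^2)))
})

test_that("both statistics are translation invariant and scale with deviations", {
  b <- simulate_beats(control_params(), hf_only_mod(), duration_s = 300)
  shifted <- beat_series(b$time_s, b$rr_ms + 200)
  expect_equal(sdnn(shifted), sdnn(b))
  expect_equal(rmssd(shifted), rmssd(b))
  mu <- mean(b$rr_ms)
  scaled <- beat_series(b$time_s, mu + 2 * (b$rr_ms - mu))
  expect_equal(sdnn(scaled), 2 * sdnn(b))
  expect_equal(rmssd(scaled), 2 * rmssd(b))
})

test_that("a clean series passes through the artifact filter untouched", {
  b <- simulate_beats(control_params(), lf_only_mod(), duration_s = 300)
  out <- clean_beats(b)
  rep <- cleaning_report(out)
  expect_equal(rep$pct_interpolated, 0)
  expect_length(rep$replaced, 0)
  expect_equal(out$rr_ms, b$rr_ms)
})

test_that("an isolated doubled beat is replaced by its neighbor midpoint", {
  rr <- c(rep(780, 8), 1600, rep(820, 11))
  b <- beat_series(seq(0, by = 0.8, length.out = 20), rr)
  out <- clean_beats(b, rel_threshold = 0.3)
  rep <- cleaning_report(out)
  expect_equal(rep$replaced, 9L)
  expect_equal(out$rr_ms[9], (780 + 820) / 2)  # midpoint of leading/trailing beats
  expect_equal(out$rr_ms[-9], b$rr_ms[-9])
})

test_that("seeded ectopic beats are detected against generator ground truth", {
  b <- simulate_beats(control_params(),
                      modulation_spec(mp_lf_amp = 2, m_lf_amp = 0.002,
                                      mp_hf_amp = 2),
                      duration_s = 600)
  ect <- inject_artifacts(b, fraction = 0.02, kind = "ectopic_short_long", seed = 1)
  out <- clean_beats(ect, rel_threshold = 0.3)
  detected <- cleaning_report(out)$replaced
  truth <- which(!ect$valid)
  expect_gte(length(intersect(truth, detected)) / length(truth), 0.9)
})

test_that("heavy contamination raises a quality warning, not a failure", {
  rr <- rep(800, 100)
  rr[seq(5, 95, by = 10)] <- 1600
  b <- beat_series(seq(0, by = 0.8, length.out = 100), rr)
  expect_warning(out <- clean_beats(b), class = "hrvmech_quality_warning")
  expect_true(cleaning_report(out)$quality_flag)
})

test_that("segmentation follows the 5-min 50%-overlap scheme", {
  b30 <- simulate_beats(control_params(), lf_only_mod(), duration_s = 1800)
  seg <- segment_beats(b30)
  expect_equal(nrow(seg), 11)
  expect_equal(seg$start_s, seq(0, 1500, by = 150))
  expect_false(attr(seg, "short_record"))

  b5 <- simulate_beats(control_params(), duration_s = 300)
  expect_equal(nrow(segment_beats(b5)), 1)

  b10 <- simulate_beats(control_params(), duration_s = 600)
  disjoint <- segment_beats(b10, overlap = 0)
  expect_equal(nrow(disjoint), 2)
  expect_lt(max(disjoint$beats[[1]]$time_s), 300)
  expect_gte(min(disjoint$beats[[2]]$time_s), 300)

  short <- segment_beats(simulate_beats(control_params(), duration_s = 120))
  expect_true(attr(short, "short_record"))
  expect_equal(nrow(short), 1)
})

test_that("the time-domain summary averages per-segment statistics", {
  b <- simulate_beats(control_params(), duration_s = 1800)
  tm <- hrv_time(b)
  expect_equal(tm$n_segments, 11)
  expect_equal(tm$sdnn_ms, 0)
  expect_equal(tm$rmssd_ms, 0)
  expect_equal(tm$sdnn_ms, mean(tidy(tm)$sdnn_ms))
  expect_named(glance(tm),
               c("sdnn_ms", "rmssd_ms", "n_segments", "pct_interpolated"))

  # RMSSD weights fast variability: HF drive beats LF drive of equal
  # peak-to-trough amplitude (both 111 ms by the closed form)
  hf <- hrv_time(simulate_beats(control_params(), hf_only_mod(), 600))
  lf <- hrv_time(simulate_beats(control_params(),
                                modulation_spec(mp_lf_amp = 2), 600))
  expect_gt(hf$rmssd_ms, 0)
  expect_gt(hf$rmssd_ms, lf$rmssd_ms)
  expect_equal(hf$sdnn_ms, lf$sdnn_ms, tolerance = 0.05)
})

test_that("stationary periodic series give segment means equal to the whole-record value", {
  b <- sinusoid_beats(1800, function(t) 850 + 60 * sin(2 * pi * 0.1 * t))
  tm <- hrv_time(b, clean = FALSE)
  expect_equal(tm$sdnn_ms, sdnn(b), tolerance = 0.01)
})
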