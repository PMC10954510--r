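test_that("heart period and rate follow the closed-form automaticity model", {
  ctrl <- heart_period(control_params())
  expect_equal(ctrl$hp_ms, 855.5556, tolerance = 1e-6)
  expect_equal(heart_rate(control_params())$hr_bpm, 70.12987, tolerance = 1e-6)

  # unit-slope identity
  expect_equal(heart_period(sinus_params(tsys = 0, th = -40, mp = -41, m = 1))$hp_ms, 1)
  expect_equal(heart_rate(sinus_params(tsys = 0, th = -100, mp = -200, m = 1/6))$hr_bpm, 100)

  # sympathetic parameters shorten the period and raise the rate
  symp <- sinus_params(mp = -55, m = 0.046)
  expect_equal(heart_period(symp)$hp_ms, 626.0870, tolerance = 1e-6)
  expect_lt(heart_period(symp)$hp_ms, ctrl$hp_ms)
  vag <- sinus_params(mp = -65, m = 0.026)
  expect_equal(heart_rate(vag)$hr_bpm, 47.56098, tolerance = 1e-6)
  expect_lt(heart_rate(vag)$hr_bpm, 70.13)

  # HR x HP identity
  joined <- predict_variability(sinus_params(dmp = 1, dm = 0.001))
  expect_equal(joined$hp_ms * joined$hr_bpm, 60000)
})

test_that("non-firing parameterizations are rejected", {
  expect_error(heart_period(sinus_params(mp = -35)), "non-firing")
  expect_error(heart_period(sinus_params(mp = -40)), "non-firing")
  expect_error(sinus_params(m = 0), "non-firing|> 0")
  expect_error(hp_variability(sinus_params(dmp = 2, dm = 0.04)), "dm too large")
  expect_error(hp_variability(sinus_params(dmp = 25, dm = 0.001)), "dmp too large")
})

test_that("variability magnitudes match direct evaluation of the extremes", {
  lf <- sinus_params(dmp = 2, dm = 0.002)
  expect_equal(hp_variability(lf)$dhp_ms, 173.3746, tolerance = 1e-5)
  expect_equal(hr_variability(lf)$dhr_bpm, 14.19698, tolerance = 1e-5)

  hf <- sinus_params(dmp = 2, dm = 0)
  expect_equal(hp_variability(hf)$dhp_ms, 2 * 2 / 0.036, tolerance = 1e-9)

  low <- sinus_params(mp = -63, m = 0.032, dmp = 2, dm = 0.001)
  expect_equal(hr_variability(low)$dhr_bpm, 9.850265, tolerance = 1e-5)

  none <- sinus_params(dmp = 0, dm = 0)
  expect_equal(hp_variability(none)$dhp_ms, 0)
  expect_equal(hr_variability(none)$dhr_bpm, 0)
})

test_that("variability equals brute-force extremes of period/rate (property)", {
  p <- random_param_sets(200)
  got <- predict_variability(p)
  # independent oracle: evaluate the period/rate at the two opposed
  # parameter excursions (in-phase mp and m swings) and take the magnitude
  hp_short <- heart_period(dplyr::mutate(p, mp = mp + dmp, m = m + dm, dmp = 0, dm = 0))$hp_ms
  hp_long <- heart_period(dplyr::mutate(p, mp = mp - dmp, m = m - dm, dmp = 0, dm = 0))$hp_ms
  expect_equal(got$dhp_ms, abs(hp_long - hp_short), tolerance = 1e-10)
  hr_fast <- heart_rate(dplyr::mutate(p, mp = mp + dmp, m = m + dm, dmp = 0, dm = 0))$hr_bpm
  hr_slow <- heart_rate(dplyr::mutate(p, mp = mp - dmp, m = m - dm, dmp = 0, dm = 0))$hr_bpm
  expect_equal(got$dhr_bpm, abs(hr_fast - hr_slow), tolerance = 1e-10)
})

test_that("systole duration cancels in heart-period variability", {
  for (ts in c(0, 300, 1000)) {
    p <- sinus_params(tsys = ts, dmp = 2, dm = 0.002)
    expect_equal(hp_variability(p)$dhp_ms, 173.3746, tolerance = 1e-5)
  }
  # ... but not in heart-rate variability
  d0 <- hr_variability(sinus_params(tsys = 0, dmp = 2, dm = 0.002))$dhr_bpm
  d300 <- hr_variability(sinus_params(tsys = 300, dmp = 2, dm = 0.002))$dhr_bpm
  expect_false(isTRUE(all.equal(d0, d300)))
})

test_that("scenario presets carry the canonical parameters and predictions", {
  pre <- scenario_presets()
  expect_equal(nrow(pre), 6)
  expect_true(all(pre$dm[pre$band == "hf"] == 0))
  expect_true(all(pre$tsys == 300 & pre$th == -40 & pre$dmp == 2))

  pred <- predict_variability(pre)
  val <- function(sc, bd, col) pred[[col]][pred$scenario == sc & pred$band == bd]
  expect_equal(round(val("control", "lf", "dhp_ms")), 173)
  expect_equal(round(val("high_sna_low_pna", "lf", "dhp_ms")), 165)
  expect_equal(round(val("low_sna_high_pna", "hf", "dhp_ms")), 125)
})

test_that("sweeps are consistent with the point predictions and monotone", {
  sw <- sweep_dm(control_params(), dm_grid = seq(0, 0.005, by = 0.0005))
  expect_equal(sw$dhp_ms[sw$dm == 0], 111.1111, tolerance = 1e-4)
  expect_equal(sw$dhp_ms[sw$dm == 0.002],
               hp_variability(sinus_params(dmp = 2, dm = 0.002))$dhp_ms)
  expect_true(all(diff(sw$dhp_ms) >= 0))
  expect_true(all(diff(sw$dhr_bpm) >= 0))
  expect_error(sweep_dm(control_params(), dm_grid = c(0, 0.04)), "grid")

  sd <- sweep_dmp(control_params(), dmp_grid = 0:4)
  expect_equal(sd$dhp_ms[sd$dmp == 0], 0)
  expect_equal(sd$dhr_bpm[sd$dmp == 0], 0)
  # exact linearity of the heart-period response in dmp
  expect_equal(sd$dhp_ms, 2 * (0:4) / 0.036, tolerance = 1e-12)
  expect_equal(sd$dhp_ms[sd$dmp == 4], 2 * sd$dhp_ms[sd$dmp == 2])
  expect_error(sweep_dmp(control_params(), dmp_grid = c(0, 20)), "grid")
})

test_that("the rendered action-potential trajectory honors the model timing", {
  wf <- ap_waveform(control_params(), n_beats = 3, dt = 1)
  hp <- heart_period(control_params())$hp_ms
  ramp <- dplyr::filter(wf, beat == 1, phase == "diastole")
  expect_equal(max(ramp$time_ms), 20 / 0.036, tolerance = 1e-9) # 555.56 ms
  expect_equal(min(wf$vm_mv), -60)
  expect_equal(max(ramp$vm_mv), -40)
  onsets <- tapply(wf$time_ms, wf$beat, min)
  expect_equal(as.numeric(diff(onsets)), rep(hp, 2), tolerance = 1e-9)
})
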