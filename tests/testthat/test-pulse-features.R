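test_that("zero-phase low-pass preserves DC and the passband, kills the stopband", {
  wc <- pressure_waveform(rep(93.3, 2000), 1000)
  expect_equal(lowpass_filter(wc, 30)$samples, rep(93.3, 2000),
               tolerance = 1e-9)
  t <- seq(0, 4 - 1e-3, by = 1e-3)
  w5 <- pressure_waveform(100 + 10 * sin(2 * pi * 5 * t), 1000)
  y5 <- lowpass_filter(w5, 30)$samples
  core <- 500:3500
  amp5 <- (max(y5[core]) - min(y5[core])) / 2
  expect_equal(amp5, 10, tolerance = 0.01)
  w100 <- pressure_waveform(100 + 10 * sin(2 * pi * 100 * t), 1000)
  y100 <- lowpass_filter(w100, 30)$samples
  amp100 <- (max(y100[core]) - min(y100[core])) / 2
  expect_lt(amp100, 10 / 10)   # > 20 dB attenuation
  expect_error(lowpass_filter(w5, 600), "Nyquist")
})

test_that("the clinical MAP formula is exact arithmetic", {
  expect_equal(round(map_formula(120, 80), 1), 93.3)
  expect_identical(map_formula(97, 97), 97)
  expect_identical(map_formula(100, 70), 80)
  expect_error(map_formula(70, 100), "sbp")
})

test_that("augmentation index is the AP/PP percentage", {
  expect_equal(aix(5.3, 40), 13.25)
  expect_identical(aix(0, 40), 0)
  expect_equal(aix(10, 40), 25)
  expect_error(aix(1, 0), "positive")
  expect_error(aix(-1, 40), "\\[0, pp\\]")
  expect_error(aix(41, 40), "\\[0, pp\\]")
})

test_that("aortic wave speed is 87 % of the carotid-femoral value", {
  expect_equal(round(cfpwv_to_apwv(7.52), 2), 6.54)
  expect_equal(cfpwv_to_apwv(10), 8.7)
  x <- c(3, 6.2, 11)
  expect_true(all(cfpwv_to_apwv(x) < x))
  expect_error(cfpwv_to_apwv(0), "positive")
})

test_that("sinusoid features match the closed form", {
  w <- generate_fixture("sinusoid")
  ft <- extract_features(w)
  expect_equal(ft$sbp, 120, tolerance = 0.01)
  expect_equal(ft$dbp, 80, tolerance = 0.01)
  expect_equal(ft$pp, 40, tolerance = 0.02)
  expect_equal(ft$map_integral, 100, tolerance = 0.05)
  expect_equal(ft$map_formula, 93.33, tolerance = 0.02)
  expect_true(ft$dbp <= ft$map_integral && ft$map_integral <= ft$sbp)
  expect_equal(ft$pp, ft$sbp - ft$dbp, tolerance = 1e-9)
})

test_that("features are offset-invariant except for the pressure levels", {
  w <- std_sim()$waveforms$aa
  w25 <- pressure_waveform(w$samples + 25, w$sample_rate,
                           w$sensor_position, w$t0)
  f0 <- extract_features(w)
  f25 <- extract_features(w25)
  expect_equal(f25$sbp, f0$sbp + 25, tolerance = 1e-6)
  expect_equal(f25$dbp, f0$dbp + 25, tolerance = 1e-6)
  expect_equal(f25$pp, f0$pp, tolerance = 1e-6)
  expect_equal(f25$ap, f0$ap, tolerance = 1e-6)
  expect_equal(f25$aix, f0$aix, tolerance = 1e-6)
  expect_equal(f25$foot_time, f0$foot_time)
})

test_that("per-beat extraction agrees with whole-signal extrema", {
  w <- generate_fixture("gaussian_pulse_train")
  ft <- extract_features(w, filter = FALSE)
  expect_equal(ft$sbp, max(w$samples), tolerance = 0.02)
  expect_equal(ft$dbp, min(w$samples), tolerance = 0.02)
})

test_that("the standard waveform yields the bench augmentation values", {
  ft <- std_features()
  expect_false(is.na(ft$ap))
  expect_equal(ft$ap, 5.3, tolerance = 0.3)
  expect_equal(ft$aix, 13.3, tolerance = 3 / 13.3)
  expect_equal(ft$map_formula, map_formula(ft$sbp, ft$dbp), tolerance = 1e-9)
})

test_that("feature extraction needs at least one full beat", {
  flat <- pressure_waveform(rep(90, 500), 1000)
  expect_error(extract_features(flat), "beat")
})

test_that("both foot definitions segment the standard waveform", {
  w <- std_sim()$waveforms$aa
  fl <- foot_times(w)
  ftan <- foot_times(w, method = "tangent")
  expect_equal(length(fl), length(ftan))
  expect_true(all(abs(fl - ftan) < 0.05))
  # feet are one period apart
  expect_equal(diff(fl), rep(0.8, length(fl) - 1), tolerance = 0.01)
})

test_that("feature invariants hold across fixtures and the simulator", {
  cases <- list(generate_fixture("sinusoid"),
                generate_fixture("gaussian_pulse_train"),
                generate_fixture("standard_like"),
                std_sim()$waveforms$aa,
                std_sim()$waveforms$ab)
  for (w in cases) {
    ft <- extract_features(w)
    expect_true(ft$dbp <= ft$map_integral + 1e-9)
    expect_true(ft$map_integral <= ft$sbp + 1e-9)
    expect_equal(ft$pp, ft$sbp - ft$dbp, tolerance = 1e-9)
    if (!is.na(ft$ap)) {
      expect_true(ft$ap >= 0 && ft$ap <= ft$pp + 1e-9)
      # beat-averaged aix vs ratio of beat-averaged ap/pp agree closely
      expect_equal(ft$aix, 100 * ft$ap / ft$pp, tolerance = 1e-4)
    }
  }
})
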