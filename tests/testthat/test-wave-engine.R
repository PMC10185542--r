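test_that("characteristic impedance follows the transmission-line closure", {
  # hand evaluation with the 133.322 Pa/mmHg conversion:
  # 1000 * 6.54 / (pi * 0.014^2) = 1.0621e7 Pa.s/m^3 = 0.0797 mmHg.s/mL
  expect_equal(characteristic_impedance(0.028, 6.54, 1000), 0.07966,
               tolerance = 1e-3)
  z <- characteristic_impedance(0.02, 5, 1000)
  expect_equal(characteristic_impedance(0.02 * sqrt(2), 5, 1000), z / 2,
               tolerance = 1e-12)
  expect_equal(characteristic_impedance(0.02, 10, 1000), 2 * z,
               tolerance = 1e-12)
  expect_error(characteristic_impedance(0, 5, 1000), "positive")
})

test_that("reflection coefficient has matched, closed and open limits", {
  expect_identical(reflection_coefficient(1, 1), 0)
  expect_identical(reflection_coefficient(1, Inf), 1)
  expect_equal(reflection_coefficient(1, 3), 0.5)
  expect_equal(reflection_coefficient(2, 0), -1)
  set.seed(7)
  for (i in 1:20) {
    g <- reflection_coefficient(runif(1, 0.01, 2), runif(1, 0, 50))
    expect_true(g > -1 && g <= 1)
  }
})

test_that("the orifice law anchors at 15 % and orders the sweep", {
  expect_equal(terminal_resistance(0.15, 1.3), 1.3)
  expect_equal(terminal_resistance(0, 2), 2 * 0.85^2)
  r <- terminal_resistance(seq(0.05, 0.25, by = 0.05), 1)
  expect_true(all(diff(r) > 0))
  expect_error(terminal_resistance(1, 1), "unbounded")
})

test_that("the standard simulation produces a physiological waveform", {
  sim <- std_sim()
  expect_s3_class(sim, "aorta_simulation")
  expect_named(sim$waveforms, c("aa", "ab"))
  w <- sim$waveforms$aa
  expect_true(all(is.finite(w$samples)))
  expect_equal(length(w$samples), 3 * 0.8 * 4000)
  expect_equal(sim$wave_speed,
               moens_pwv(346e3, 0.002, 1000, 0.0218, 0.5))
  # pressures stay inside a plausible physiological envelope
  expect_true(min(w$samples) > 40 && max(w$samples) < 200)
})

test_that("a matched load removes the reflected component", {
  simM <- matched_sim()
  expect_equal(simM$gamma_ab, 0)
  aa <- simM$waveforms$aa$samples
  ab <- simM$waveforms$ab$samples
  # identical shape up to the pure propagation delay
  lag <- 0.551 / simM$wave_speed * 4000
  i <- seq(ceiling(lag) + 1, length(aa))
  shifted <- approx(seq_along(aa), aa, xout = i - lag)$y
  expect_lt(max(abs(ab[i] - shifted)), 0.05)
  ft <- extract_features(simM$waveforms$aa)
  expect_true(is.na(ft$ap) || ft$ap < 1.5)
})

test_that("pulse pressure amplifies toward the bifurcation", {
  sensors <- c(s0 = 0, s1 = 0.15, s2 = 0.3, s3 = 0.45, s4 = 0.6)
  sim <- simulate_aorta(sensors = sensors)
  pp <- vapply(sim$waveforms,
               function(w) extract_features(w)$pp, numeric(1))
  expect_true(all(diff(pp) > 0))
})

test_that("foot-to-foot transit time recovers constructed and analytic delays", {
  fx <- generate_fixture("shifted_pair")
  m <- measure_ptt(fx$a, fx$b, distance = 0.5)
  expect_equal(m$ptt, fx$delay, tolerance = 1e-3 / fx$delay)
  expect_equal(m$pwv, 10, tolerance = 0.03)
  # identical waveforms: no causal delay
  expect_error(measure_ptt(fx$a, fx$a, 0.5), "causal|delay")
  # delay-line equivalence on the simulator: PTT = distance / c within
  # one sample period
  sim <- std_sim()
  pt <- measure_ptt(sim$waveforms$aa, sim$waveforms$ab, 0.551)
  expect_lt(abs(pt$ptt - 0.551 / sim$wave_speed), 1 / 4000)
})

test_that("unstable and degenerate configurations are rejected", {
  st <- simulation_settings(root_reflection_coefficient = 1.1)
  load <- peripheral_load()
  load$terminal_resistance <- 1e9   # Gamma ~ 1
  expect_error(simulate_aorta(load = load, settings = st), "unstable")
  expect_error(simulation_settings(sample_rate = 100), "200")
  expect_error(simulation_settings(n_beats = 2), "3")
  expect_error(pressure_waveform(c(1, NA), 100), "finite")
})

test_that("reflection truncation bound is met at the shipped defaults", {
  sim <- std_sim()
  g <- abs(sim$gamma_ab * sim$settings$root_reflection_coefficient)
  expect_lt(g^sim$settings$n_reflections, 1e-3)
})

test_that("retained beats are periodic at beat-commensurate sampling", {
  for (hr in c(60, 75, 100)) {
    sim <- if (hr == 75) std_sim() else
      simulate_aorta(profile = cardiac_profile(hr, 70))
    w <- sim$waveforms$aa$samples
    nT <- round(60 / hr * 4000)
    nb <- length(w) %/% nT
    last <- w[((nb - 1) * nT + 1):(nb * nT)]
    prev <- w[((nb - 2) * nT + 1):((nb - 1) * nT)]
    expect_lt(max(abs(last - prev)), 0.1)
  }
})

test_that("equal IVP and EVP changes only shift the pressure level", {
  levels <- c(40, 80, 120)
  sims <- lapply(levels, function(lv)
    simulate_aorta(pressures = chamber_pressures(lv, lv)))
  ref <- sims[[1]]$waveforms$aa$samples - levels[1]
  for (k in 2:3) {
    shifted <- sims[[k]]$waveforms$aa$samples - levels[k]
    expect_lt(max(abs(shifted - ref)), 0.1)
  }
  ptts <- vapply(sims, function(s)
    measure_ptt(s$waveforms$aa, s$waveforms$ab, 0.551)$ptt, numeric(1))
  expect_equal(max(ptts) - min(ptts), 0)
})

test_that("raising transmural pressure slows the waves", {
  base <- aortasim_defaults()$ivp_offset
  s0 <- std_sim()
  s10 <- simulate_aorta(pressures = chamber_pressures(base + 10, base))
  expect_lt(s10$wave_speed, s0$wave_speed)
  expect_gt(measure_ptt(s10$waveforms$aa, s10$waveforms$ab, 0.551)$ptt,
            measure_ptt(s0$waveforms$aa, s0$waveforms$ab, 0.551)$ptt)
})

test_that("wave speed converted from transit times matches the bench table", {
  expect_equal(round(pwv_from_ptt(0.551, 0.0838), 2), 6.58)
  expect_equal(round(pwv_from_ptt(0.551, 0.1079), 2), 5.11)
  expect_equal(round(pwv_from_ptt(0.551, 0.1763), 2), 3.13)
  expect_error(pwv_from_ptt(0.551, 0), "positive")
})
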