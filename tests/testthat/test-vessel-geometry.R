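test_that("standard aorta reproduces the fabricated dimensions", {
  geo <- build_standard_aorta()
  expect_equal(geo$total_length, 0.743, tolerance = 1e-12)
  expect_true(all(vapply(geo$segments, `[[`, numeric(1),
                         "wall_thickness") == 0.002))
  expect_equal(geo$bifurcation_angle, 80)
  expect_equal(geo$sensor_distance_aa_ab, 0.551)
  expect_equal(diff(geo$sensor_positions), rep(0.1, 7), tolerance = 1e-9)
  expect_true(all(geo$sensor_positions >= 0 &
                    geo$sensor_positions <= geo$total_length))
  # arch is a half circle of 50 mm radius; femoral branch is the remainder
  expect_equal(geo$segments[[1]]$length, pi * 0.05, tolerance = 1e-12)
  expect_equal(geo$segments[[2]]$length, 0.512)
  expect_equal(geo$reflection_site, pi * 0.05 + 0.512, tolerance = 1e-12)
})

test_that("the three path-length constants stay distinct", {
  lens <- standard_aorta_lengths()
  expect_equal(unname(lens["total"]), 0.743)
  expect_equal(unname(lens["ptt_reference"]), 0.712)
  expect_equal(unname(lens["sensor_aa_ab"]), 0.551)
  expect_equal(length(unique(lens)), 3L)
})

test_that("diameter_at follows the piecewise-linear taper", {
  geo <- build_standard_aorta()
  expect_equal(diameter_at(geo, 0), 0.028)
  # abdominal midpoint: 26 -> 16 mm taper gives 21 mm
  mid <- geo$segment_starts[2] + 0.512 / 2
  expect_equal(diameter_at(geo, mid), 0.021, tolerance = 1e-12)
  # end of the abdominal segment belongs to it: distal 16 mm
  expect_equal(diameter_at(geo, geo$reflection_site), 0.016)
  expect_equal(diameter_at(geo, geo$total_length), 0.014)
  expect_error(diameter_at(geo, -0.01), "out of range")
  expect_error(diameter_at(geo, 1), "out of range")
})

test_that("diameter_at is continuous within a segment and bounded", {
  geo <- build_standard_aorta()
  s <- seq(geo$segment_starts[2] + 1e-6, geo$reflection_site - 1e-6,
           length.out = 101)
  d <- diameter_at(geo, s)
  expect_true(all(d <= 0.026 + 1e-12 & d >= 0.016 - 1e-12))
  expect_true(all(abs(diff(d)) < 1e-3))  # no jumps inside the segment
  expect_true(all(diff(d) < 0))          # monotone taper
})

test_that("effective_diameter matches a fine Riemann sum and its bounds", {
  geo <- build_standard_aorta()
  seg2_start <- geo$segment_starts[2]
  # uniform segment: any interval returns that diameter
  expect_equal(effective_diameter(geo, 0.01, 0.1), 0.028)
  # full abdominal taper: mean of 26 and 16 mm
  expect_equal(effective_diameter(geo, seg2_start, geo$reflection_site),
               0.021, tolerance = 1e-12)
  # root-to-bifurcation path against an independent Riemann oracle
  s <- seq(0, geo$reflection_site, length.out = 20001)
  smid <- (s[-1] + s[-length(s)]) / 2
  oracle <- mean(diameter_at(geo, smid))
  got <- effective_diameter(geo, 0, geo$reflection_site)
  expect_equal(got, oracle, tolerance = 1e-4)
  expect_true(got > 0.016 && got < 0.028)
  expect_error(effective_diameter(geo, 0.2, 0.2), "degenerate")
})

test_that("effective_diameter is invariant under interval subdivision", {
  geo <- build_standard_aorta()
  s0 <- 0.05
  s1 <- 0.65
  full <- effective_diameter(geo, s0, s1)
  for (cut in c(0.157, 0.3, 0.5)) {
    left <- effective_diameter(geo, s0, cut)
    right <- effective_diameter(geo, cut, s1)
    recombined <- (left * (cut - s0) + right * (s1 - cut)) / (s1 - s0)
    expect_equal(recombined, full, tolerance = 1e-12)
  }
})

test_that("segment and geometry validation rejects bad inputs", {
  expect_error(vessel_segment("x", -1, 0.02, 0.02, 0.002), "positive")
  expect_error(vessel_segment("x", 0.1, 0.02, 0.02, 0), "positive")
  geo <- build_standard_aorta()
  expect_error(aorta_geometry(geo$segments, 80, c(-0.1), 0.551),
               "sensor positions")
})
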