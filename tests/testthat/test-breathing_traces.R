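test_that("sinusoid traces follow the platform encoding", {
  for (spec in list(c(3, 1), c(4, 2), c(5, 4))) {
    tr <- make_sinusoid(spec[1], spec[2], duration_s = 6 * spec[1])
    expect_equal(min(tr$values), 0)
    expect_equal(max(tr$values), 2)
    expect_equal(tr$up_scale_cm, spec[2] / 2)
    expect_equal(tr$down_scale_cm, spec[2] / 2)
  }
  # quarter period of a home-ascending sine reaches the maximum encoding
  tr4 <- make_sinusoid(4, 2, duration_s = 20)
  expect_lt(abs(trace_value_at(tr4, 1) - 2), 1e-3)
  # 3 s at 30 ms steps -> 100 samples
  expect_length(make_sinusoid(1, 1, duration_s = 3)$values, 100)
  expect_error(make_sinusoid(-1, 1, 10), "period")
  expect_error(make_sinusoid(3, 1, -5), "duration")
})

test_that("scaled values map to physical displacement piecewise-linearly", {
  tr <- breathing_trace(c(0, 0.5, 1, 1.5, 2), up_scale_cm = 1.28,
                        down_scale_cm = 1.62)
  expect_equal(to_physical(tr), c(-1.62, -0.81, 0, 0.64, 1.28))
  # monotone and bounded by the scales
  v <- seq(0, 2, by = 0.01)
  ph <- to_physical(tr, v)
  expect_true(all(diff(ph) >= 0))
  expect_true(all(ph >= -1.62 - 1e-12 & ph <= 1.28 + 1e-12))
})

test_that("the platform clamp rejects excursions beyond 4 cm", {
  expect_error(breathing_trace(c(0, 1, 2), up_scale_cm = 5, down_scale_cm = 1),
               "platform limit")
  expect_error(breathing_trace(c(0, 1, 2.5)), "\\[0, 2\\]")
  expect_error(patient_trace_spec(max_down_cm = 4.5), "platform limit")
})

test_that("patient-like traces reproduce the target motion statistics", {
  for (seed in c(1L, 7L, 99L)) {
    tr <- make_patient_like(patient_trace_spec(seed = seed))
    ph <- to_physical(tr)
    expect_equal(max(ph) - min(ph), 2.90, tolerance = 1e-12)
    expect_equal(max(ph), 1.28)
    expect_equal(min(ph), -1.62)
    expect_identical(detect_cycles(tr)$n_cycles, 43L)
    expect_length(tr$values, round(153 / 0.030))
  }
})

test_that("patient-like generation is seed-reproducible and loops seamlessly", {
  a <- make_patient_like(patient_trace_spec(seed = 11L))
  b <- make_patient_like(patient_trace_spec(seed = 11L))
  expect_identical(a$values, b$values)
  c2 <- make_patient_like(patient_trace_spec(seed = 12L))
  expect_false(identical(a$values, c2$values))
  # both ends sit on the exhale plateau: matching displacement, ~zero slope
  n <- length(a$values)
  expect_lt(abs(a$values[n] - a$values[1]), 0.1)
  slope_end <- diff(a$values[c(n - 1, n)])
  slope_start <- diff(a$values[c(1, 2)])
  expect_lt(abs(slope_end - slope_start), 0.05)
})

test_that("infeasible patient specs are rejected", {
  expect_error(patient_trace_spec(duration_s = 30, n_cycles = 40),
               "infeasible")
})

test_that("cycle detection recovers sinusoid periods within a sample", {
  tr <- make_sinusoid(4, 2, duration_s = 20)
  cy <- detect_cycles(tr)
  expect_lt(abs(cy$mean_period_s - 4), 0.03)
  # the commissioning gate: measured period within 0.1 s of applied
  cy3 <- detect_cycles(make_sinusoid(3, 1, duration_s = 30))
  expect_lt(abs(cy3$mean_period_s - 3), 0.1)
  expect_error(detect_cycles(breathing_trace(rep(1, 100))), "peaks")
})

test_that("trace CSV round-trips and rejects malformed files", {
  tr <- make_sinusoid(4, 2, duration_s = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(path, tr)
  back <- read_trace(path)
  expect_equal(back$values, tr$values, tolerance = 1e-6)
  expect_equal(back$up_scale_cm, 1)
  expect_equal(back$sample_interval_s, 0.030)
  # out-of-range value
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,value", "0.000000,0.5", "0.030000,2.5"), bad)
  expect_error(read_trace(bad), "outside \\[0, 2\\]")
  # missing header
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.000000,0.5", "0.030000,1.5"), bad2)
  expect_error(read_trace(bad2), "header")
})

test_that("looping traces wrap and non-looping traces refuse extrapolation", {
  tr <- make_patient_like(patient_trace_spec(seed = 3L))
  expect_equal(trace_value_at(tr, 153 + 10), trace_value_at(tr, 10))
  sin_tr <- make_sinusoid(4, 2, duration_s = 12)
  expect_error(trace_value_at(sin_tr, 100), "loop")
})
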