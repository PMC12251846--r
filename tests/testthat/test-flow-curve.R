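test_that("flow_curve rejects physically invalid profiles", {
  expect_error(flow_curve(c(0, 1), c(0, 1, 2)), "same length")
  expect_error(flow_curve(0, 0), "at least 2")
  expect_error(flow_curve(c(0, 1, 1, 2), c(0, 1, 2, 3)), "strictly increasing")
  expect_error(flow_curve(c(1, 2), c(0, 1)), "start at 0")
  expect_error(flow_curve(c(0, 1), c(0, -1)), "non-negative")
  expect_error(flow_curve(c(0, 1), c(5, 1)), "rest")
})

test_that("peak_inspiratory_flow breaks ties towards the earliest point", {
  fc <- flow_curve(c(0, 1, 2, 3), c(0, 30, 30, 10))
  p <- peak_inspiratory_flow(fc)
  expect_equal(p$index, 2L)
  expect_equal(p$time_to_pif, 1)
  expect_equal(p$pif, 30)
})

test_that("flow from pressure drop is delta_p / R and validates inputs", {
  expect_equal(flow_from_pressure(0), 0)
  expect_equal(flow_from_pressure(6, device_resistance(2)), 3)
  x <- c(0, 1.3, 42, 100)
  expect_equal(flow_from_pressure(x), x)               # R = 1 identity
  expect_equal(flow_from_pressure(2 * x), 2 * flow_from_pressure(x))  # linear
  expect_error(flow_from_pressure(-1), "non-negative")
  expect_error(device_resistance(0), "positive")
  expect_error(device_resistance(-2), "positive")
})

test_that("slope decomposition is segmentwise difference quotients", {
  fc <- flow_curve(c(0, 1, 2), c(0, 10, 10))
  expect_equal(decompose_slopes(fc), c(10, 0))
  const <- flow_curve(c(0, 1, 2, 4), c(0, 0, 0, 0))
  expect_equal(decompose_slopes(const), c(0, 0, 0))
})

test_that("decompose/recompose round-trip is the identity on valid curves", {
  set.seed(11)
  for (i in 1:25) {
    fc <- random_curve(n = sample(5:20, 1))
    rt <- recompose_from_slopes(fc$flows[1], decompose_slopes(fc), fc$times)
    expect_equal(rt$flows, fc$flows)
    expect_equal(rt$times, fc$times)
  }
})

test_that("recomposition clamps negative flows at zero and records it", {
  rc <- recompose_from_slopes(0, c(10, -20), c(0, 1, 2))
  expect_equal(rc$flows, c(0, 10, 0))
  expect_equal(attr(rc, "n_clamped"), 1L)
  flat <- recompose_from_slopes(0, c(0, 0, 0), c(0, 1, 2, 3))
  expect_equal(flat$flows, rep(0, 4))
  expect_error(recompose_from_slopes(0, c(1, 2), c(0, 1)), "length")
})

test_that("inhaled volume is the unit-consistent trapezoidal area", {
  expect_equal(inhaled_volume(flow_curve(c(0, 60), c(0, 2))), 1)  # triangle
  expect_equal(inhaled_volume(flow_curve(c(0, 1, 2), c(0, 0, 0))), 0)
  # dense-quadrature oracle on 18-point reference curves
  for (fc in list(moderate_profile(), severe_profile())) {
    v <- inhaled_volume(fc)
    expect_lt(abs(v - dense_riemann_volume(fc)) / v, 1e-9)
  }
})

test_that("inhaled volume is additive, monotone and scale-equivariant", {
  set.seed(23)
  for (i in 1:10) {
    fc <- random_curve(n = 12)
    j <- sample(2:11, 1)
    left <- flow_curve(fc$times[1:j], fc$flows[1:j])
    right_t <- fc$times[j:12] - fc$times[j]
    right_f <- fc$flows[j:12]
    # right half may not start at rest; integrate it directly
    right_v <- sum(diff(right_t) *
                     (right_f[-length(right_f)] + right_f[-1]) / 2) / 60
    expect_equal(inhaled_volume(left) + right_v, inhaled_volume(fc))
    # scale equivariance
    scaled <- flow_curve(fc$times, 3.5 * fc$flows)
    expect_equal(inhaled_volume(scaled), 3.5 * inhaled_volume(fc))
    # pointwise-larger flows give at least the volume
    bigger <- flow_curve(fc$times, fc$flows + c(0, rep(2, 11)))
    expect_gte(inhaled_volume(bigger), inhaled_volume(fc))
  }
})

test_that("profiles survive a CSV round-trip", {
  fc <- moderate_profile()
  path <- withr::local_tempfile(fileext = ".csv")
  write_flow_curve(fc, path)
  back <- read_flow_curve(path)
  expect_equal(back$times, fc$times, tolerance = 1e-6)
  expect_equal(back$flows, fc$flows, tolerance = 1e-6)
  expect_equal(readLines(path, n = 1), "time_s,flow_lpm")
})
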