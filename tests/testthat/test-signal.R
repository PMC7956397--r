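test_that("window segmentation tiles the recording and discards the tail", {
  mk <- function(n) accel_recording(
    matrix(0, n, 3, dimnames = list(NULL, c("ax", "ay", "az"))))

  g <- segment_windows(mk(2500), 4)
  expect_equal(nrow(g), 25L)
  expect_equal(g$end_sample - g$start_sample + 1L, rep(100L, 25L))

  expect_equal(nrow(segment_windows(mk(10), 0.4)), 1L)

  # a 12.3-minute recording at WS 4 s
  expect_equal(nrow(segment_windows(mk(738 * 25), 4)), 184L)

  # tiling: consecutive, non-overlapping, anchored at sample 1
  for (ws in c(0.4, 2, 4, 6.8, 10)) {
    g <- segment_windows(mk(3000), ws)
    expect_equal(g$start_sample[1], 1L)
    expect_equal(g$start_sample[-1], g$end_sample[-nrow(g)] + 1L)
    expect_equal(nrow(g), floor(3000 / round(ws * 25)))
    expect_equal(g$end_s - g$start_s, rep(round(ws * 25) / 25, nrow(g)))
  }

  expect_error(segment_windows(mk(50), 4), "too short")
  expect_error(segment_windows(mk(50), 0.017), "does not map")
})

test_that("orientation feature is the windowed mean of the longitudinal axis", {
  rec <- accel_recording(cbind(ax = rep(1, 100), ay = 0, az = 0))
  expect_equal(orientation_feature(rec, 4), 1)

  rec <- accel_recording(cbind(ax = rep(0, 100), ay = 1, az = 0))
  expect_equal(orientation_feature(rec, 4), 0)

  rec <- accel_recording(cbind(ax = rep(c(0.9, 0.7), 50), ay = 0, az = 0))
  expect_equal(orientation_feature(rec, 4), 0.8)

  # respects axis_roles: longitudinal mapped onto az
  rec <- accel_recording(cbind(ax = rep(0, 100), ay = 0, az = 0.5),
                         axis_roles = c(longitudinal = "az",
                                        anterior_posterior = "ay",
                                        medio_lateral = "ax"))
  expect_equal(orientation_feature(rec, 2), rep(0.5, 2))

  # bounded by min/max of the longitudinal samples
  set.seed(41)
  v <- runif(500, -1, 1)
  rec <- accel_recording(cbind(ax = v, ay = 0, az = 0))
  o <- orientation_feature(rec, 2)
  g <- segment_windows(rec, 2)
  for (w in seq_len(nrow(g))) {
    seg <- v[g$start_sample[w]:g$end_sample[w]]
    expect_gte(o[w], min(seg))
    expect_lte(o[w], max(seg))
  }
})

test_that("activity counts match a direct difference-equation oracle", {
  fs <- 25
  t <- (0:499) / fs
  bf <- signal::butter(2, c(0.25, 11) / (fs / 2), type = "pass")
  set.seed(7)
  axes <- cbind(ax = 1 + 0.1 * sin(2 * pi * 1.3 * t),
                ay = 0.4 * sin(2 * pi * 2 * t),
                az = rnorm(500, 0, 0.05))
  rec <- accel_recording(axes)

  for (mode in c("single_axis", "triaxial")) {
    got <- activity_counts(rec, 4, mode)
    want <- oracle_counts(axes, fs, 4, bf$b, bf$a, mode)
    expect_equal(got, want, tolerance = 1e-9)
    expect_true(all(got >= 0))
  }
})

test_that("counts vanish for motionless input and ignore constant offsets", {
  # all-zero window
  rec <- accel_recording(matrix(0, 200, 3,
                                dimnames = list(NULL, c("ax", "ay", "az"))))
  expect_equal(activity_counts(rec, 2, "triaxial"), rep(0, 4))

  # pure gravity (constant 1 g on every axis): DC carries no counts
  rec <- accel_recording(matrix(1, 200, 3,
                                dimnames = list(NULL, c("ax", "ay", "az"))))
  expect_equal(activity_counts(rec, 2, "triaxial"), rep(0, 4))

  # adding any constant offset up to the sensor range changes nothing
  t <- (0:499) / 25
  base <- cbind(ax = 0.3 * sin(2 * pi * 2 * t), ay = 0.2 * sin(2 * pi * 3 * t),
                az = 0)
  c0 <- activity_counts(accel_recording(base), 4, "triaxial")
  for (off in c(-7.5, -1, 0.5, 7.5)) {
    shifted <- base
    shifted[, "ay"] <- shifted[, "ay"] + off
    c1 <- activity_counts(accel_recording(shifted), 4, "triaxial")
    expect_equal(c1, c0, tolerance = 1e-12)
  }
})

test_that("counts are 1-homogeneous in the dynamic signal", {
  t <- (0:999) / 25
  set.seed(9)
  dyn <- 0.25 * sin(2 * pi * 1.7 * t) + rnorm(1000, 0, 0.02)
  mk <- function(k) accel_recording(cbind(ax = 1, ay = pmin(pmax(k * dyn, -8), 8),
                                          az = 0))
  c1 <- activity_counts(mk(1), 4, "single_axis")
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(activity_counts(mk(k), 4, "single_axis"), k * c1,
                 tolerance = 1e-9)
  }
})

test_that("per-second normalization makes counts stable under window doubling", {
  t <- (0:2999) / 25
  rec <- accel_recording(cbind(ax = 1, ay = 0.4 * sin(2 * pi * 2 * t), az = 0))
  for (ws in c(1, 2, 4)) {
    a <- mean(activity_counts(rec, ws, "single_axis"))
    b <- mean(activity_counts(rec, 2 * ws, "single_axis"))
    expect_lt(abs(a - b) / b, 0.05)
  }
})

test_that("recording construction enforces the sensor contract", {
  expect_error(accel_recording(cbind(ax = 9, ay = 0, az = 0)), "8 g")
  expect_error(accel_recording(cbind(ax = NA_real_, ay = 0, az = 0)),
               "non-finite")
  expect_error(accel_recording(cbind(ax = 1, ay = 0, az = 0),
                               axis_roles = c(longitudinal = "ax",
                                              anterior_posterior = "ax",
                                              medio_lateral = "az")),
               "bijection")
  expect_error(accel_recording(matrix(0, 0, 3,
                                      dimnames = list(NULL, c("ax", "ay", "az")))),
               "at least one sample")
})
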