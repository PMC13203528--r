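test_that("gravity fixed point: aligned static sample leaves the quaternion alone", {
  q <- c(1, 0, 0, 0)
  q2 <- madgwick_step(q, a = c(0, 0, 1), w = c(0, 0, 0))
  expect_equal(q2, q, tolerance = 1e-15)
})

test_that("beta = 0 reduces to pure gyro integration (closed form and oracle)", {
  cfg <- madgwick_config(beta = 0)
  # 1 rad/s about z for 10 s -> rotation angle 10 rad, q = [cos 5, 0, 0, sin 5]
  w <- c(0, 0, 57.29578)
  q <- c(1, 0, 0, 0)
  for (t in 1:1000) q <- madgwick_step(q, a = c(0, 0, 1), w = w, cfg)
  expect_lt(sqrt(sum((q - c(cos(5), 0, 0, sin(5)))^2)), 1e-2)
  # random gyro stream vs the independent Euler integrator
  set.seed(5)
  wseq <- matrix(rnorm(300, 0, 50), 100, 3)
  q1 <- c(1, 0, 0, 0)
  for (t in 1:100) q1 <- madgwick_step(q1, a = c(0, 0, 1), w = wseq[t, ], cfg)
  expect_equal(q1, gyro_integrate(c(1, 0, 0, 0), wseq, cfg$dt),
               tolerance = 1e-12)
})

test_that("free-fall gating: below-threshold acceleration gives the gyro-only update bit-for-bit", {
  cfg <- madgwick_config()
  set.seed(6)
  q <- quat_normalize(rnorm(4))
  w <- rnorm(3, 0, 100)
  a_small <- c(0.03, -0.04, 0.05)  # ||a|| ~ 0.07 g <= epsilon
  got <- madgwick_step(q, a_small, w, cfg)
  wr <- w * pi / 180
  qd <- 0.5 * quat_multiply(q, c(0, wr))
  ref <- (q + qd * cfg$dt) / sqrt(sum((q + qd * cfg$dt)^2))
  expect_identical(got, ref)
})

test_that("static tilt: the correction converges the predicted gravity onto the measurement", {
  q0 <- dualfall:::quat_from_euler(30 * pi / 180, 0, 0)
  ahat <- drop(t(quat_to_rotmat(q0)) %*% c(0, 0, 1))
  cfg <- madgwick_config()
  q <- c(1, 0, 0, 0)
  for (t in 1:1000) q <- madgwick_step(q, ahat, c(0, 0, 0), cfg)  # 10 s
  ghat <- quat_to_rotmat(q)[3, ]
  ang <- acos(min(1, sum(ghat * ahat))) * 180 / pi
  expect_lt(ang, 0.5)
})

test_that("sequence transform: identity statics, isometry and unit norms", {
  s <- static_stream(0, 0, n = 200)
  df <- madgwick_transform(s$a, s$w)
  expect_equal(df$a_global, df$a_body, tolerance = 1e-12)
  set.seed(7)
  a <- matrix(rnorm(600, 0, 0.5), 200, 3); a[, 3] <- a[, 3] + 1
  w <- matrix(rnorm(600, 0, 80), 200, 3)
  df2 <- madgwick_transform(a, w)
  expect_lt(max(abs(sqrt(rowSums(df2$a_global^2)) - sqrt(rowSums(a^2)))), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(df2$w_global^2)) - sqrt(rowSums(w^2)))), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(df2$quaternions^2)) - 1)), 1e-9)
})

test_that("gravity alignment: a 35-degree compound tilt ends up vertical in the global frame", {
  s <- static_stream(20, 28.7, n = 1200)  # ~35 degrees total tilt
  df <- madgwick_transform(s$a, s$w)
  tail_a <- df$a_global[1000:1200, ]
  ang <- acos(pmin(1, tail_a[, 3] / sqrt(rowSums(tail_a^2)))) * 180 / pi
  expect_lt(max(ang), 0.5)
})

test_that("non-finite samples are rejected with the sample index", {
  s <- static_stream(0, 0, n = 50)
  s$a[17, 2] <- NaN
  expect_error(madgwick_transform(s$a, s$w), "17")
})

test_that("convergence detection: aligned stream, 90-degree tilt, and non-converging rotation", {
  s <- static_stream(0, 0, n = 300)
  df <- madgwick_transform(s$a, s$w)
  expect_equal(detect_convergence(df), 0.5)
  s90 <- static_stream(90, 0, n = 1600)  # 16 s of static samples
  df90 <- madgwick_transform(s90$a, s90$w)
  tc <- detect_convergence(df90)
  expect_false(is.na(tc))
  expect_lte(tc, 15)
  # perpetual tumbling with no usable gravity reference never satisfies the hold
  n <- 600
  w <- matrix(rep(c(200, 0, 0), each = n), n, 3)
  a <- matrix(0, n, 3)  # free fall throughout: gate keeps the gyro-only path
  dfr <- madgwick_transform(a, w)
  expect_true(is.na(detect_convergence(dfr)))
  expect_error(detect_convergence(madgwick_transform(s$a[1:20, ], s$w[1:20, ])),
               "hold window")
})

test_that("roll/pitch wearing offsets collapse onto one vertical trace in the global frame", {
  cfg <- synth_config(noise_sd = c(accel = 0.005, gyro = 0.2),
                      pre_fall_s = c(4, 5))
  pr <- generate_paired_fall("forward", cfg, offset_a = c(0, 0, 0),
                             offset_b = c(20, 15, 0), trial_seed = 31)
  dfa <- madgwick_transform(pr$a$samples[, 1:3], pr$a$samples[, 4:6])
  dfb <- madgwick_transform(pr$b$samples[, 1:3], pr$b$samples[, 4:6])
  onset <- pr$a$onset_frame
  n <- min(nrow(dfa$a_global), nrow(dfb$a_global))
  idx <- onset:n  # after the quiet warm-up phase
  # body-frame vertical channels disagree badly; global-frame ones agree
  dis_body <- mean(abs(dfa$a_body[idx, 3] - dfb$a_body[idx, 3]))
  dis_glob <- mean(abs(dfa$a_global[idx, 3] - dfb$a_global[idx, 3]))
  expect_lt(dis_glob, 0.08)
  expect_gt(dis_body, dis_glob)
})
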