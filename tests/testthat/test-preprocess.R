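test_that("causal Butterworth filter: DC, stopband and passband behavior", {
  fs <- 100
  n <- 1000
  tt <- seq_len(n) / fs
  # DC preserved in steady state
  const <- matrix(2.5, n, 2)
  out <- butterworth_lowpass(const, fs)
  expect_equal(out[(n - 100):n, ], const[(n - 100):n, ], tolerance = 1e-6)
  # 20 Hz = 2.5x cutoff: at least the analytic 4th-order attenuation
  s20 <- matrix(sin(2 * pi * 20 * tt), n, 1)
  o20 <- butterworth_lowpass(s20, fs)
  analytic <- 1 / sqrt(1 + 2.5^8)  # |H| of the analog prototype at 2.5 fc
  expect_lte(max(abs(o20[500:n, 1])), analytic)
  # 1 Hz passes within 1%
  s1 <- matrix(sin(2 * pi * 1 * tt), n, 1)
  o1 <- butterworth_lowpass(s1, fs)
  expect_equal(max(abs(o1[500:n, 1])), 1, tolerance = 0.01)
  expect_error(butterworth_lowpass(s1, fs, fc = 60), "Nyquist")
})

make_fall_trial <- function(n = 600, impact = 500, onset = 430) {
  set.seed(42)
  imu_trial(matrix(rnorm(n * 6), n, 6), "S01", "F01", is_fall = TRUE,
            onset_frame = onset, impact_frame = impact, trial_id = "S01_F01")
}

test_that("pre-impact truncation removes the margin and excludes short trials", {
  cfg <- windowing_config()
  tr <- truncate_pre_impact(make_fall_trial(impact = 500), cfg)
  expect_equal(nrow(tr$samples), 475)
  expect_message(
    out <- truncate_pre_impact(make_fall_trial(n = 150, impact = 100,
                                               onset = 60), cfg),
    "excluding")
  expect_null(out)
  adl <- imu_trial(matrix(0, 300, 6), "S01", "D01")
  expect_identical(truncate_pre_impact(adl, cfg), adl)
})

test_that("window geometry matches the printed formulas and the loop oracle", {
  cfg <- windowing_config()
  expect_equal(cfg$n_win, 87)
  expect_equal(cfg$step, 34)
  expect_equal(reverse_windows(87, cfg), cbind(start = 1L, end = 87L))
  rw <- reverse_windows(121, cfg)
  expect_equal(sort(rw[, "end"]), c(87L, 121L))
  rw475 <- reverse_windows(475, cfg)
  expect_equal(nrow(rw475), 12)
  expect_equal(min(rw475[, "start"]), 475 - 87 - 11 * 34 + 1)
  expect_gte(min(rw475[, "start"]), 1)
  # brute-force enumeration of the reverse loop on random lengths
  set.seed(8)
  for (n in sample(1:600, 40)) {
    got <- reverse_windows(n, cfg)
    ora <- reverse_windows_oracle(n, cfg$n_win, cfg$step)
    expect_equal(nrow(got), nrow(ora))
    if (nrow(ora)) expect_equal(unname(got), unname(ora))
  }
})

test_that("forward windows keep the initial segment, reverse keeps the terminal one", {
  cfg <- windowing_config()
  expect_equal(nrow(forward_windows(87, cfg)), 1)
  expect_equal(unname(forward_windows(120, cfg)), cbind(1L, 87L))
  expect_equal(unname(forward_windows(121, cfg)),
               cbind(c(1L, 35L), c(87L, 121L)))
  set.seed(9)
  for (n in sample(87:600, 30)) {
    fw <- forward_windows(n, cfg)
    rw <- reverse_windows(n, cfg)
    expect_equal(nrow(fw), nrow(rw))  # same count, offset anchoring differs
    expect_equal(unname(fw[1, "start"]), 1L)          # initial segment kept
    expect_equal(unname(rw[1, "end"]), as.integer(n)) # terminal anchor
    if ((n - cfg$n_win) %% cfg$step == 0)
      expect_equal(unname(fw), unname(rw[nrow(rw):1, , drop = FALSE]))
  }
})

test_that("window labels follow the inclusive overlap rule", {
  cfg <- windowing_config()
  tr <- truncate_pre_impact(make_fall_trial(n = 600, impact = 500,
                                            onset = 300), cfg)
  expect_equal(label_window(c(310, 396), tr, cfg), 1L)  # wholly inside phase
  expect_equal(label_window(c(1, 87), tr, cfg), 0L)     # wholly before onset
  # exactly threshold overlap (ceiling(87/2) = 44 samples) is a fall
  tr2 <- tr; tr2$onset_frame <- 475L - 43L
  expect_equal(label_window(c(475 - 86, 475), tr2, cfg), 1L)
  tr3 <- tr; tr3$onset_frame <- 475L - 42L  # 43/87 < 0.5
  expect_equal(label_window(c(475 - 86, 475), tr3, cfg), 0L)
  adl <- imu_trial(matrix(0, 300, 6), "S01", "D01")
  expect_equal(label_window(c(1, 87), adl, cfg), 0L)
})

test_that("dataset construction: counts, cutoff safety and determinism", {
  cfg <- windowing_config()
  fall <- make_fall_trial(n = 600, impact = 500, onset = 380)
  ws <- build_dataset(list(fall), cfg)
  expect_equal(n_windows(ws), 12)   # truncated length 475
  expect_true(all(ws$end_index <= 475))  # nothing crosses the cutoff
  expect_equal(n_windows(build_dataset(list(), cfg)), 0)
  # mixed synthetic set: fall windows are a small minority
  ds <- generate_dataset(synth_config(n_subjects = 2, seed = 3))
  wsm <- build_dataset(ds$trials, cfg)
  expect_lt(sum(wsm$label == 1), 0.2 * sum(wsm$label == 0))
  # deterministic given identical inputs
  ws2 <- build_dataset(list(fall), cfg)
  expect_identical(ws$x, ws2$x)
  expect_identical(ws$label, ws2$label)
})

test_that("dual-frame windows carry all four streams with shared geometry", {
  cfg <- windowing_config()
  ds <- generate_dataset(synth_config(n_subjects = 1,
                                      trials_per_subject = c(n_adl = 1, n_fall = 1),
                                      seed = 4))
  ws <- build_dataset(ds$trials, cfg)
  expect_named(ws$x, c("ba", "bg", "ga", "gg"))
  for (s in names(ws$x))
    expect_equal(dim(ws$x[[s]])[1:2], c(3, cfg$n_win))
  # rotation isometry survives windowing: per-sample accel norms match
  nb <- sqrt(colSums(ws$x$ba[, , 1]^2))
  ng <- sqrt(colSums(ws$x$ga[, , 1]^2))
  expect_equal(nb, ng, tolerance = 1e-9)
})
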