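test_that("static generation is exact at zero noise and offset", {
  cfg <- synth_config(noise_sd = c(accel = 0, gyro = 0),
                      adl_duration_s = c(5, 5))
  tr <- generate_adl_trial("static", cfg, trial_seed = 1)
  expect_equal(tr$samples[, 1:3],
               matrix(rep(c(0, 0, 1), each = 500), 500, 3), tolerance = 1e-12)
  expect_equal(tr$samples[, 4:6], matrix(0, 500, 3), tolerance = 1e-12)
})

test_that("walking trials put their spectral peak at the gait frequency", {
  cfg <- synth_config(adl_duration_s = c(20, 20))
  tr <- generate_adl_trial("walk", cfg, trial_seed = 2)
  f <- attr(tr, "gait_hz")
  nrm <- sqrt(rowSums(tr$samples[, 1:3]^2))
  x <- nrm - mean(nrm)
  sp <- Mod(fft(x))^2
  freqs <- (seq_along(x) - 1) * tr$fs / length(x)
  keep <- freqs > 0.5 & freqs < 10
  peak <- freqs[keep][which.max(sp[keep])]
  expect_lt(abs(peak - f), 0.15)
})

test_that("low-dynamic kinds keep the specific-force magnitude near 1 g", {
  cfg <- synth_config(adl_duration_s = c(10, 12))
  for (kind in c("static", "walk", "sit_stand")) {
    tr <- generate_adl_trial(kind, cfg, offset_deg = c(10, -8, 20),
                             trial_seed = 3)
    expect_equal(mean(sqrt(rowSums(tr$samples[, 1:3]^2))), 1, tolerance = 0.05)
  }
})

test_that("fall trials show the descent dip, post-impact spike and ordering", {
  cfg <- synth_config()
  for (dir in c("forward", "backward", "lateral")) {
    tr <- generate_fall_trial(dir, cfg, trial_seed = 4)
    expect_lt(tr$onset_frame, tr$impact_frame)
    nrm <- sqrt(rowSums(tr$samples[, 1:3]^2))
    descent <- tr$onset_frame:tr$impact_frame
    expect_lt(min(nrm[descent]), 0.6)  # partial free-fall signature
    spike <- (tr$impact_frame + 1):(tr$impact_frame + 5)
    expect_gt(max(nrm[spike]), 2)      # impact lies after the annotation
    # pre-impact truncation removes the spike entirely
    cut <- truncate_pre_impact(tr, windowing_config())
    expect_lt(max(sqrt(rowSums(cut$samples[, 1:3]^2))), 2)
  }
})

test_that("datasets are reproducible and fully annotated", {
  cfg <- synth_config(n_subjects = 2, seed = 77)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$trials[[3]]$samples, d2$trials[[3]]$samples)
  expect_equal(nrow(d1$manifest),
               2 * sum(cfg$trials_per_subject))
  falls <- d1$manifest[d1$manifest$is_fall, ]
  expect_true(all(falls$onset_frame < falls$impact_frame))
})

test_that("integrating the generated gyro recovers the generating orientation", {
  cfg <- synth_config(noise_sd = c(accel = 0, gyro = 0), pre_fall_s = c(2, 2))
  tr <- generate_fall_trial("forward", cfg, offset_deg = c(15, -10, 25),
                            trial_seed = 8)
  qtrue <- attr(tr, "quaternions")
  q <- qtrue[1, ]
  q <- gyro_integrate(q, tr$samples[-nrow(tr$samples), 4:6], 1 / cfg$fs)
  # angular error between integrated and generating attitude
  qerr <- quat_multiply(quat_conjugate(q), qtrue[nrow(qtrue), ])
  ang <- 2 * acos(min(1, abs(qerr[1]))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("paired trials share the motion and differ only by wearing offset", {
  cfg <- synth_config(noise_sd = c(accel = 0, gyro = 0))
  pr <- generate_paired_fall("forward", cfg, offset_a = c(0, 0, 0),
                             offset_b = c(20, 15, 30), trial_seed = 9)
  expect_equal(pr$a$onset_frame, pr$b$onset_frame)
  expect_equal(pr$a$impact_frame, pr$b$impact_frame)
  expect_false(isTRUE(all.equal(pr$a$samples, pr$b$samples)))
  pr2 <- generate_paired_fall("forward", cfg, offset_a = c(5, 5, 5),
                              offset_b = c(5, 5, 5), trial_seed = 9)
  expect_equal(pr2$a$samples, pr2$b$samples, tolerance = 1e-12)
})
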