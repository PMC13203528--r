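test_that("window metrics match the printed formulas and brute-force counting", {
  m <- window_metrics(c(0.9, 0.8), c(1, 1))
  expect_equal(m$accuracy, 1); expect_equal(m$f1, 1)
  m2 <- window_metrics(c(0.1, 0.2, 0.3), c(1, 0, 1))
  expect_equal(m2$recall, 0); expect_equal(m2$specificity, 1)
  expect_equal(m2$f1, 0)  # precision + recall = 0 convention
  # printed counts TP=8, FP=2, FN=1, TN=9
  probs <- c(rep(0.9, 8), rep(0.9, 2), rep(0.1, 1), rep(0.1, 9))
  labs <- c(rep(1, 8), rep(0, 2), rep(1, 1), rep(0, 9))
  m3 <- window_metrics(probs, labs)
  expect_equal(m3$precision, 0.8)
  expect_equal(m3$recall, 8 / 9)
  expect_equal(m3$f1, 2 * (0.8 * 8 / 9) / (0.8 + 8 / 9))
  # brute-force counting oracle on random vectors
  set.seed(10)
  for (i in 1:10) {
    p <- runif(50); l <- rbinom(50, 1, 0.4)
    mm <- window_metrics(p, l)
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (j in 1:50) {
      pred <- p[j] > 0.5
      if (pred && l[j] == 1) tp <- tp + 1
      if (pred && l[j] == 0) fp <- fp + 1
      if (!pred && l[j] == 1) fn <- fn + 1
      if (!pred && l[j] == 0) tn <- tn + 1
    }
    expect_equal(mm$counts, list(TP = tp, TN = tn, FP = fp, FN = fn))
    expect_equal(mm$accuracy, (tp + tn) / 50)
  }
  expect_error(window_metrics(numeric(0), numeric(0)), "empty")
})

test_that("trial max-voting: max semantics, inclusive threshold, recall dominance", {
  probs <- c(0.1, 0.1, 0.9, 0.1)
  tm <- trial_max_voting(probs, rep("t1", 4), rep(1, 4))
  expect_equal(tm$decisions$decision, 1L)
  tm2 <- trial_max_voting(c(0.5, 0.2), c("t1", "t1"), c(1, 1))
  expect_equal(tm2$decisions$decision, 1L)  # exactly 0.5 declares a fall
  # dominance: trial recall >= window recall for identical predictions
  set.seed(11)
  for (i in 1:10) {
    n_tr <- 8
    sizes <- sample(2:6, n_tr, replace = TRUE)
    tid <- rep(paste0("t", seq_len(n_tr)), sizes)
    tlab <- rep(rbinom(n_tr, 1, 0.5), sizes)
    if (all(tlab == 0) || all(tlab == 1)) next
    p <- runif(length(tid))
    wm <- window_metrics(p, tlab)
    tm3 <- trial_max_voting(p, tid, tlab)
    expect_gte(tm3$recall, wm$recall)
  }
  expect_error(trial_max_voting(0.4, "t1", numeric(0)))
})

test_that("threshold sweep: recall never rises, specificity never falls", {
  set.seed(12)
  p <- runif(200); l <- rbinom(200, 1, 0.3)
  ths <- seq(0.05, 0.95, by = 0.05)
  rec <- sapply(ths, function(th) window_metrics(p, l, th)$recall)
  spe <- sapply(ths, function(th) window_metrics(p, l, th)$specificity)
  expect_true(all(diff(rec) <= 1e-12))
  expect_true(all(diff(spe) >= -1e-12))
})

test_that("per-activity false-positive table reproduces grouped rates", {
  dec <- c(rep(1, 13), rep(0, 146), rep(0, 50))
  act <- c(rep("stumble", 159), rep("walk", 50))
  tab <- per_activity_fp(dec, act)
  st <- tab[tab$activity == "stumble", ]
  expect_equal(st$trials, 159); expect_equal(st$fp, 13)
  expect_equal(st$fp_rate_pct, 8.18)
  expect_equal(tab[tab$activity == "walk", "fp_rate_pct"], 0)
  tot <- tab[tab$activity == "Total", ]
  expect_equal(tot$fp_rate_pct, round(100 * 13 / 209, 2))
  # rates recomputed from counts agree to 2 decimals
  expect_equal(tab$fp_rate_pct, round(100 * tab$fp / tab$trials, 2))
})

# stub models keyed on window content (rolling inference takes any object
# with a predict method returning fall probabilities)
predict.always_fall <- function(object, newdata, ...) rep(1, dim(newdata$ba)[3])
predict.never_fall <- function(object, newdata, ...) rep(0, dim(newdata$ba)[3])
predict.gyro_gate <- function(object, newdata, ...) {
  apply(newdata$bg, 3, function(m) as.numeric(max(abs(m)) > object$th))
}

test_that("rolling inference: degenerate models bound the lead time", {
  registerS3method("predict", "always_fall", predict.always_fall)
  registerS3method("predict", "never_fall", predict.never_fall)
  cfg <- windowing_config()
  tr <- generate_fall_trial("forward", synth_config(seed = 5),
                            trial_seed = 50)
  m1 <- structure(list(), class = "always_fall")
  r1 <- rolling_inference(tr, m1, cfg, lowpass = FALSE)
  expect_true(r1$detected)
  expect_equal(r1$t_alarm, cfg$n_win / tr$fs)  # first full window
  expect_equal(r1$lead, r1$t_impact - cfg$n_win / tr$fs)
  expect_gt(r1$lead, 0)
  m0 <- structure(list(), class = "never_fall")
  r0 <- rolling_inference(tr, m0, cfg, lowpass = FALSE)
  expect_false(r0$detected)
  expect_true(is.na(r0$lead))
})

test_that("rolling inference never touches samples at or after the impact", {
  registerS3method("predict", "always_fall", predict.always_fall)
  tr <- generate_fall_trial("forward", synth_config(seed = 6), trial_seed = 60)
  tr$samples[tr$impact_frame:nrow(tr$samples), ] <- NaN  # poison post-impact data
  m1 <- structure(list(), class = "always_fall")
  expect_no_error(r <- rolling_inference(tr, m1, windowing_config()))
  expect_true(r$detected)
})

test_that("rolling inference alarms within one stride of a known signature", {
  registerS3method("predict", "gyro_gate", predict.gyro_gate)
  cfg <- windowing_config()
  # quiet trial with a strong gyro burst starting at sample 300
  n <- 500; sig_start <- 300
  sm <- cbind(matrix(0, n, 2), rep(1, n), matrix(0, n, 3))
  sm[sig_start:n, 4] <- 200
  tr <- imu_trial(sm, "S01", "F01", is_fall = TRUE, onset_frame = sig_start,
                  impact_frame = 480L)
  m <- structure(list(th = 50), class = "gyro_gate")
  r <- rolling_inference(tr, m, cfg, lowpass = FALSE)
  ends <- forward_windows(479, cfg)[, "end"]
  expected_end <- min(ends[ends >= sig_start])
  expect_equal(r$t_alarm, expected_end / 100)
  expect_lte(r$t_alarm - sig_start / 100, cfg$step / 100)
})

test_that("lead-time summaries aggregate detections, compliance and the ECDF", {
  mk <- function(lead) structure(list(trial_id = "t", detected = !is.na(lead),
                                      t_impact = 5, t_alarm = 5 - lead,
                                      lead = lead),
                                 class = "lead_time_result")
  miss <- lead_time_summary(list(mk(NA), mk(NA)))
  expect_equal(miss$detection_rate, 0)
  expect_true(is.na(miss$median_lead_ms))
  s <- lead_time_summary(list(mk(0.3), mk(0.4), mk(0.5)))
  expect_equal(s$median_lead_ms, 400)
  expect_equal(unname(s$compliance[">=250ms"]), 1)
  expect_equal(s$ecdf(max(500)), 1)
  expect_error(lead_time_summary(list()), "no results")
})
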