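# metrics from confusion counts; F1 = 0 when precision + recall = 0
confusion_metrics <- function(TP, FP, FN, TN) {
  acc <- (TP + TN) / (TP + TN + FP + FN)
  rec <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spe <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0)
    2 * prec * rec / (prec + rec) else 0
  list(counts = list(TP = TP, TN = TN, FP = FP, FN = FN),
       accuracy = acc, recall = rec, specificity = spe, precision = prec,
       f1 = f1)
}

#' Window-level classification metrics
#'
#' Confusion counts and the standard metric set (accuracy, recall,
#' specificity, precision, F1) of thresholded window probabilities.
#'
#' @param probs Fall probabilities, one per window.
#' @param labels True 0/1 labels.
#' @param threshold Decision threshold; a window is called a fall when its
#'   probability exceeds the threshold (strictly).
#' @return A list with `counts` and the metrics.
#' @export
window_metrics <- function(probs, labels, threshold = 0.5) {
  if (!length(probs)) stop("empty input")
  stopifnot(length(probs) == length(labels))
  pred <- as.integer(probs > threshold)
  confusion_metrics(TP = sum(pred == 1 & labels == 1),
                    FP = sum(pred == 1 & labels == 0),
                    FN = sum(pred == 0 & labels == 1),
                    TN = sum(pred == 0 & labels == 0))
}

#' Trial-wise max-voting decisions and metrics
#'
#' The score of a trial is the maximum fall probability over its windows;
#' the trial is declared a fall when the score is not lower than the
#' threshold (inclusive). Mirrors the deployment logic of alarming on the
#' first window above threshold.
#'
#' @param probs Window fall probabilities.
#' @param trial_id Trial identifier per window.
#' @param trial_label True trial label per window (0 = ADL, 1 = fall);
#'   must be constant within a trial.
#' @param threshold Decision threshold (inclusive).
#' @return A list with `decisions` (data frame: trial, score, decision,
#'   label), `counts` and trial-level metrics.
#' @export
trial_max_voting <- function(probs, trial_id, trial_label, threshold = 0.5) {
  stopifnot(length(probs) == length(trial_id),
            length(probs) == length(trial_label))
  if (!length(probs)) stop("empty input")
  score <- tapply(probs, trial_id, max)
  lab <- tapply(trial_label, trial_id, function(l) {
    u <- unique(l)
    if (length(u) != 1) stop("trial label must be constant within a trial")
    u
  })
  lab <- lab[names(score)]
  dec <- as.integer(score >= threshold)
  m <- confusion_metrics(TP = sum(dec == 1 & lab == 1),
                         FP = sum(dec == 1 & lab == 0),
                         FN = sum(dec == 0 & lab == 1),
                         TN = sum(dec == 0 & lab == 0))
  m$decisions <- data.frame(trial = names(score), score = as.numeric(score),
                            decision = dec, label = as.integer(lab),
                            row.names = NULL)
  m
}

#' Per-activity false-positive table for ADL trials
#'
#' Groups trial-level decisions of ADL trials by activity code and reports
#' trial counts, false positives and FP rates, with an overall row.
#'
#' @param decisions Integer 0/1 trial decisions (1 = declared fall).
#' @param activity Activity code per trial.
#' @return A data frame with columns `activity`, `trials`, `fp`,
#'   `fp_rate_pct`; the last row (`activity == "Total"`) is the overall
#'   rate.
#' @export
per_activity_fp <- function(decisions, activity) {
  stopifnot(length(decisions) == length(activity))
  n <- tapply(decisions, activity, length)
  fp <- tapply(decisions, activity, sum)
  out <- data.frame(activity = names(n), trials = as.integer(n),
                    fp = as.integer(fp),
                    fp_rate_pct = round(100 * as.integer(fp) / as.integer(n), 2),
                    row.names = NULL)
  rbind(out, data.frame(activity = "Total", trials = sum(out$trials),
                        fp = sum(out$fp),
                        fp_rate_pct = round(100 * sum(out$fp) / sum(out$trials), 2)))
}

#' Rolling forward inference and pre-impact lead time
#'
#' Replays deployment on a full (untruncated) fall trial: the complete
#' pre-impact sequence is low-pass filtered and Madgwick-transformed with
#' continuous filter state, then an 87-sample window advances from the
#' recording start with a 34-sample stride, never touching any sample at
#' or after the impact frame. The alarm time is the end time of the first
#' window whose fall probability strictly exceeds the threshold; the lead
#' time is `t_impact - t_alarm`.
#'
#' @param trial A fall [imu_trial()] with `impact_frame` set.
#' @param model A fitted `fallnet`.
#' @param cfg A [windowing_config()].
#' @param madgwick_cfg A [madgwick_config()].
#' @param threshold Alarm threshold (strict).
#' @param lowpass Apply the Butterworth stage (default TRUE).
#' @return A list of class `lead_time_result`: `trial_id`, `t_alarm` (s or
#'   `NA`), `t_impact` (s), `lead` (s or `NA`), `detected`, and `reason`
#'   for misses.
#' @export
rolling_inference <- function(trial, model, cfg = windowing_config(),
                              madgwick_cfg = madgwick_config(),
                              threshold = 0.5, lowpass = TRUE) {
  stopifnot(inherits(trial, "imu_trial"), trial$is_fall)
  fs <- trial$fs
  t_impact <- trial$impact_frame / fs
  n_pre <- trial$impact_frame - 1L  # everything strictly before impact
  res <- list(trial_id = trial$trial_id, t_alarm = NA_real_,
              t_impact = t_impact, lead = NA_real_, detected = FALSE,
              reason = NA_character_)
  class(res) <- "lead_time_result"
  if (n_pre < cfg$n_win) {
    res$reason <- "trial shorter than one window before impact"
    return(res)
  }
  sm <- trial$samples[seq_len(n_pre), , drop = FALSE]
  if (lowpass) sm <- butterworth_lowpass(sm, fs = fs)
  df <- madgwick_transform(sm[, 1:3, drop = FALSE], sm[, 4:6, drop = FALSE],
                           madgwick_cfg)
  win <- forward_windows(n_pre, cfg)
  nw <- nrow(win)
  xs <- list(ba = array(0, c(3, cfg$n_win, nw)), bg = array(0, c(3, cfg$n_win, nw)),
             ga = array(0, c(3, cfg$n_win, nw)), gg = array(0, c(3, cfg$n_win, nw)))
  for (i in seq_len(nw)) {
    idx <- win[i, 1]:win[i, 2]
    xs$ba[, , i] <- t(df$a_body[idx, ]); xs$bg[, , i] <- t(df$w_body[idx, ])
    xs$ga[, , i] <- t(df$a_global[idx, ]); xs$gg[, , i] <- t(df$w_global[idx, ])
  }
  probs <- predict(model, xs, type = "prob")
  hit <- which(probs > threshold)
  if (length(hit)) {
    res$t_alarm <- unname(win[hit[1], 2]) / fs
    res$lead <- t_impact - res$t_alarm
    res$detected <- TRUE
  } else res$reason <- "no window probability above threshold"
  res
}

#' Summarize lead-time results
#'
#' @param results List of `lead_time_result` objects.
#' @param compliance_ms Lead-time levels (ms) at which to report the
#'   fraction of detected trials with lead time at least that level.
#' @return A list with `n_trials`, `detected`, `detection_rate`,
#'   `median_lead_ms`, `mean_lead_ms`, `compliance` (named fractions) and
#'   `ecdf` (function over lead times in ms); lead statistics are `NA`
#'   when nothing was detected.
#' @export
lead_time_summary <- function(results, compliance_ms = c(100, 150, 200, 250)) {
  if (!length(results)) stop("no results to summarize")
  det <- vapply(results, function(r) isTRUE(r$detected), logical(1))
  leads <- vapply(results[det], function(r) r$lead, numeric(1)) * 1000
  out <- list(n_trials = length(results), detected = sum(det),
              detection_rate = mean(det))
  if (length(leads)) {
    out$median_lead_ms <- stats::median(leads)
    out$mean_lead_ms <- mean(leads)
    out$compliance <- vapply(compliance_ms, function(th) mean(leads >= th),
                             numeric(1))
    names(out$compliance) <- paste0(">=", compliance_ms, "ms")
    out$ecdf <- stats::ecdf(leads)
  } else {
    out$median_lead_ms <- NA_real_
    out$mean_lead_ms <- NA_real_
    out$compliance <- stats::setNames(rep(NA_real_, length(compliance_ms)),
                                      paste0(">=", compliance_ms, "ms"))
    out$ecdf <- NULL
  }
  out
}
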