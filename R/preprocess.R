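#' Construct an annotated IMU trial
#'
#' @param samples T x 6 numeric matrix: columns ax, ay, az (g) then
#'   wx, wy, wz (deg/s).
#' @param subject_id Subject identifier.
#' @param activity_code Activity code (e.g. `"D02"`, `"F01"`).
#' @param is_fall Logical; fall trials must carry onset/impact annotations.
#' @param fs Sampling rate in Hz (100 for the supported recordings).
#' @param onset_frame 1-based index of the fall-phase start, or `NA`.
#' @param impact_frame 1-based index of the impact sample, or `NA`.
#' @param trial_id Optional trial identifier; derived from subject/activity
#'   if missing.
#' @return An object of class `imu_trial`.
#' @export
imu_trial <- function(samples, subject_id, activity_code, is_fall = FALSE,
                      fs = 100, onset_frame = NA_integer_,
                      impact_frame = NA_integer_, trial_id = NULL) {
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) == 6, fs > 0)
  if (is_fall) {
    if (is.na(impact_frame) || is.na(onset_frame))
      stop("fall trials require onset_frame and impact_frame")
    if (!(onset_frame < impact_frame && impact_frame <= nrow(samples)))
      stop("fall annotations must satisfy onset_frame < impact_frame <= T")
  }
  if (is.null(trial_id)) trial_id <- paste(subject_id, activity_code, sep = "_")
  structure(list(samples = samples, subject_id = subject_id,
                 activity_code = activity_code, is_fall = is_fall, fs = fs,
                 onset_frame = as.integer(onset_frame),
                 impact_frame = as.integer(impact_frame),
                 trial_id = trial_id),
            class = "imu_trial")
}

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf("IMU trial %s: subject %s, activity %s, %d samples @ %g Hz%s\n",
              x$trial_id, x$subject_id, x$activity_code, nrow(x$samples), x$fs,
              if (x$is_fall) sprintf(" [fall: onset %d, impact %d]",
                                     x$onset_frame, x$impact_frame) else ""))
  invisible(x)
}

#' Sliding-window configuration
#'
#' Window length and stride are derived from the printed formulas:
#' `n_win = floor(window_ms * fs / 1000)` and
#' `step = floor(n_win * (1 - overlap))`. The defaults (875 ms windows,
#' 60% overlap, 250 ms pre-impact margin at 100 Hz) give 87-sample windows
#' with a 34-sample stride.
#'
#' @param window_ms Window length in milliseconds.
#' @param overlap Overlap fraction in `[0, 1)`.
#' @param margin_ms Pre-impact margin in milliseconds.
#' @param fs Sampling rate in Hz.
#' @return A list of class `windowing_config` with derived `n_win`, `step`
#'   and `margin_samples`.
#' @export
windowing_config <- function(window_ms = 875, overlap = 0.6, margin_ms = 250,
                             fs = 100) {
  stopifnot(window_ms > 0, overlap >= 0, overlap < 1, margin_ms >= 0, fs > 0)
  n_win <- floor(window_ms * fs / 1000)
  step <- floor(n_win * (1 - overlap))
  structure(list(window_ms = window_ms, overlap = overlap,
                 margin_ms = margin_ms, fs = fs, n_win = n_win, step = step,
                 margin_samples = floor(margin_ms * fs / 1000)),
            class = "windowing_config")
}

#' Causal Butterworth low-pass filtering
#'
#' Applies a single-pass (causal) low-pass Butterworth IIR filter to every
#' channel. A causal pass, rather than zero-phase forward-backward
#' filtering, keeps offline preprocessing identical to streaming
#' deployment. DC gain is 1.
#'
#' @param samples T x p numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param order Filter order (default 4).
#' @param fc Cutoff frequency in Hz (default 8); must be below `fs/2`.
#' @return Filtered matrix of the same shape.
#' @export
butterworth_lowpass <- function(samples, fs = 100, order = 4, fc = 8) {
  samples <- as.matrix(samples)
  if (fc >= fs / 2) stop("cutoff frequency must be below the Nyquist rate fs/2")
  if (nrow(samples) <= 3 * order)
    stop("sequence too short to filter (need more than ", 3 * order, " samples)")
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  out <- apply(samples, 2, function(ch) as.numeric(signal::filter(bf, ch)))
  matrix(out, nrow = nrow(samples), dimnames = dimnames(samples))
}

#' Truncate a fall trial at the pre-impact cutoff
#'
#' Removes every sample from `margin_ms` before the annotated impact
#' onwards, so windows can only see pre-impact motion. ADL trials are
#' returned unchanged. A fall trial whose truncated length is shorter than
#' one window is excluded: the function returns `NULL` with the reason in
#' `attr(, "exclusion")` via a condition message.
#'
#' @param trial An [imu_trial()].
#' @param cfg A [windowing_config()].
#' @return The truncated trial, or `NULL` if the trial is too short to hold
#'   one full window after truncation.
#' @export
truncate_pre_impact <- function(trial, cfg = windowing_config()) {
  stopifnot(inherits(trial, "imu_trial"))
  if (!trial$is_fall) return(trial)
  n_keep <- trial$impact_frame - cfg$margin_samples
  if (n_keep < cfg$n_win) {
    message(sprintf(
      "excluding trial %s: only %d samples before the pre-impact cutoff (< %d)",
      trial$trial_id, max(n_keep, 0), cfg$n_win))
    return(NULL)
  }
  out <- trial
  out$samples <- trial$samples[seq_len(n_keep), , drop = FALSE]
  out$impact_frame <- NA_integer_  # impact no longer inside the data
  attr(out, "t_cut") <- n_keep
  out
}

#' Reverse sliding-window index ranges
#'
#' Windows are anchored so that the first emitted window ends exactly at
#' the end of the (truncated) sequence, then slide backward by `step`
#' samples. Ranges are 1-based and inclusive.
#'
#' @param n Sequence length, or an [imu_trial()] whose length is used.
#' @param cfg A [windowing_config()].
#' @return Integer matrix with columns `start`, `end`; zero rows when the
#'   sequence is shorter than one window. Rows are ordered as emitted
#'   (latest window first).
#' @export
reverse_windows <- function(n, cfg = windowing_config()) {
  if (inherits(n, "imu_trial")) n <- nrow(n$samples)
  n <- as.integer(n)
  if (n < cfg$n_win)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  ends <- seq(from = n, by = -cfg$step, length.out = (n - cfg$n_win) %/% cfg$step + 1)
  cbind(start = ends - cfg$n_win + 1L, end = as.integer(ends))
}

#' Forward sliding-window index ranges
#'
#' Conventional forward sampling: windows start at the sequence beginning
#' and advance by `step`; a trailing segment shorter than one window is
#' discarded.
#'
#' @inheritParams reverse_windows
#' @return Integer matrix with columns `start`, `end` (1-based, inclusive).
#' @export
forward_windows <- function(n, cfg = windowing_config()) {
  if (inherits(n, "imu_trial")) n <- nrow(n$samples)
  n <- as.integer(n)
  if (n < cfg$n_win)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  starts <- seq(from = 1L, by = cfg$step,
                length.out = (n - cfg$n_win) %/% cfg$step + 1)
  cbind(start = as.integer(starts), end = as.integer(starts + cfg$n_win - 1L))
}

#' Label a window by its overlap with the annotated fall phase
#'
#' A window receives label 1 when at least `overlap_threshold` of its
#' length lies inside the fall phase `[onset, t_cut]` of a truncated fall
#' trial (threshold inclusive); all windows of ADL trials are 0.
#'
#' @param range Integer vector `c(start, end)` (1-based, inclusive) or a
#'   single row of a window matrix.
#' @param trial The (truncated) [imu_trial()] the window came from.
#' @param cfg A [windowing_config()].
#' @param overlap_threshold Minimum overlap fraction of the window length
#'   (default 0.5).
#' @return Integer label, 0 or 1.
#' @export
label_window <- function(range, trial, cfg = windowing_config(),
                         overlap_threshold = 0.5) {
  if (!trial$is_fall) return(0L)
  t_cut <- nrow(trial$samples)  # truncated trials end at the cutoff
  lo <- max(range[1], trial$onset_frame)
  hi <- min(range[2], t_cut)
  ov <- max(0L, hi - lo + 1L)
  as.integer(ov / cfg$n_win >= overlap_threshold)
}

# internal: construct an empty window set
new_window_set <- function(n_win) {
  structure(list(
    x = list(ba = array(0, c(3, n_win, 0)), bg = array(0, c(3, n_win, 0)),
             ga = array(0, c(3, n_win, 0)), gg = array(0, c(3, n_win, 0))),
    label = integer(0), trial_id = character(0), subject = character(0),
    activity = character(0), end_index = integer(0)),
    class = "window_set", n_win = n_win)
}

#' Number of windows in a window set
#' @param ws A `window_set`.
#' @return Integer count.
#' @export
n_windows <- function(ws) length(ws$label)

#' Subset a window set
#' @param x A `window_set`.
#' @param i Indices of windows to keep.
#' @param ... Ignored.
#' @return A `window_set` with the selected windows.
#' @export
`[.window_set` <- function(x, i, ...) {
  out <- x
  out$x <- lapply(x$x, function(a) a[, , i, drop = FALSE])
  for (f in c("label", "trial_id", "subject", "activity", "end_index"))
    out[[f]] <- x[[f]][i]
  out
}

# internal: concatenate window sets
ws_bind <- function(a, b) {
  if (n_windows(a) == 0) return(b)
  if (n_windows(b) == 0) return(a)
  out <- a
  out$x <- Map(function(u, v) {
    arr <- array(0, c(dim(u)[1:2], dim(u)[3] + dim(v)[3]))
    if (dim(u)[3] > 0) arr[, , seq_len(dim(u)[3])] <- u
    if (dim(v)[3] > 0) arr[, , dim(u)[3] + seq_len(dim(v)[3])] <- v
    arr
  }, a$x, b$x)
  for (f in c("label", "trial_id", "subject", "activity", "end_index"))
    out[[f]] <- c(a[[f]], b[[f]])
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("Window set: %d windows (%d fall, %d ADL), 4 streams of 3 x %d%s\n",
              n_windows(x), sum(x$label == 1), sum(x$label == 0),
              attr(x, "n_win"),
              if (!is.null(attr(x, "role"))) paste0(" [", attr(x, "role"), "]")
              else ""))
  invisible(x)
}

#' Build a dual-frame window dataset from annotated trials
#'
#' Runs the full preprocessing pipeline per trial, in order: pre-impact
#' truncation (falls), causal Butterworth low-pass filtering, Madgwick
#' transformation of the whole trial (filter state threaded across window
#' boundaries), then reverse sliding windows for falls and forward windows
#' for ADL trials, with overlap-based labels.
#'
#' @param trials List of [imu_trial()] objects.
#' @param cfg A [windowing_config()].
#' @param madgwick_cfg A [madgwick_config()].
#' @param overlap_threshold Label threshold, see [label_window()].
#' @param lowpass Logical; apply the Butterworth stage (default TRUE).
#' @return A `window_set` holding the four 3 x n_win streams per window
#'   (`ba`, `bg`, `ga`, `gg`: body/global x accel/gyro), labels and
#'   provenance. Excluded trials are listed in `attr(, "exclusions")`.
#' @export
build_dataset <- function(trials, cfg = windowing_config(),
                          madgwick_cfg = madgwick_config(),
                          overlap_threshold = 0.5, lowpass = TRUE) {
  ws <- new_window_set(cfg$n_win)
  excluded <- character(0)
  for (trial in trials) {
    tr <- truncate_pre_impact(trial, cfg)
    if (is.null(tr)) { excluded <- c(excluded, trial$trial_id); next }
    sm <- tr$samples
    if (lowpass) sm <- butterworth_lowpass(sm, fs = tr$fs)
    df <- madgwick_transform(sm[, 1:3, drop = FALSE], sm[, 4:6, drop = FALSE],
                             madgwick_cfg)
    win <- if (tr$is_fall) reverse_windows(nrow(sm), cfg)
           else forward_windows(nrow(sm), cfg)
    if (nrow(win) == 0) { excluded <- c(excluded, trial$trial_id); next }
    nw <- nrow(win)
    part <- new_window_set(cfg$n_win)
    part$x <- list(ba = array(0, c(3, cfg$n_win, nw)),
                   bg = array(0, c(3, cfg$n_win, nw)),
                   ga = array(0, c(3, cfg$n_win, nw)),
                   gg = array(0, c(3, cfg$n_win, nw)))
    for (i in seq_len(nw)) {
      idx <- win[i, 1]:win[i, 2]
      part$x$ba[, , i] <- t(df$a_body[idx, ])
      part$x$bg[, , i] <- t(df$w_body[idx, ])
      part$x$ga[, , i] <- t(df$a_global[idx, ])
      part$x$gg[, , i] <- t(df$w_global[idx, ])
    }
    part$label <- vapply(seq_len(nw), function(i)
      label_window(win[i, ], tr, cfg, overlap_threshold), integer(1))
    part$trial_id <- rep(tr$trial_id, nw)
    part$subject <- rep(tr$subject_id, nw)
    part$activity <- rep(tr$activity_code, nw)
    part$end_index <- win[, 2]
    ws <- ws_bind(ws, part)
  }
  attr(ws, "n_win") <- cfg$n_win
  attr(ws, "exclusions") <- excluded
  ws
}
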