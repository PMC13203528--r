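# shared fixtures built in code

# body-frame static stream at a fixed tilt: a = R^T [0,0,1], w = 0
static_stream <- function(tilt_roll_deg = 0, tilt_pitch_deg = 0, n = 500) {
  q <- dualfall:::quat_from_euler(tilt_roll_deg * pi / 180,
                                  tilt_pitch_deg * pi / 180, 0)
  R <- quat_to_rotmat(q)
  a <- matrix(rep(drop(t(R) %*% c(0, 0, 1)), each = n), n, 3)
  list(a = a, w = matrix(0, n, 3))
}

# independent Euler integrator of the gyro-only quaternion kinematics
gyro_integrate <- function(q0, w_deg, dt) {
  q <- q0
  for (t in seq_len(nrow(w_deg))) {
    wr <- w_deg[t, ] * pi / 180
    qd <- 0.5 * quat_multiply(q, c(0, wr))
    q <- q + qd * dt
    q <- q / sqrt(sum(q^2))
  }
  q
}

# brute-force transcription of the reverse sliding-window loop
reverse_windows_oracle <- function(n, n_win, step) {
  out <- NULL
  pos <- n
  while (pos - n_win >= 0) {
    out <- rbind(out, c(pos - n_win + 1, pos))
    pos <- pos - step
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# a hand-made window set with arbitrary labels (four random streams)
make_ws <- function(labels, n_win = 87, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  ws <- dualfall:::new_window_set(n_win)
  ws$x <- lapply(ws$x, function(a) array(rnorm(3 * n_win * n), c(3, n_win, n)))
  ws$label <- as.integer(labels)
  ws$trial_id <- paste0("tr", seq_len(n))
  ws$subject <- rep("S01", n)
  ws$activity <- rep("D01", n)
  ws$end_index <- rep(n_win, n)
  ws
}

# small separable window set for quick training checks: class-1 windows get
# a strong global-accel offset
make_separable_ws <- function(n_per_class = 30, n_win = 87, seed = 2) {
  ws <- make_ws(rep(c(0, 1), each = n_per_class), n_win, seed)
  idx <- which(ws$label == 1)
  ws$x$ga[, , idx] <- ws$x$ga[, , idx] + 1.5
  ws$x$bg[, , idx] <- ws$x$bg[, , idx] * 2
  ws$subject <- rep(c("S01", "S02"), length.out = length(ws$label))
  ws
}

fast_ctrl <- function(epochs = 3, ...) train_config(epochs = epochs, ...)
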