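#' Synthetic-data configuration
#'
#' Study conditions of the bundled synthetic IMU generator: 100 Hz
#' 6-channel streams, ADL trials lasting tens of seconds, fall trials
#' with an annotated instability onset, a sub-second descent toward
#' partial free fall and a post-impact spike, per-subject constant
#' wearing-orientation offsets, and gravity-consistent signals.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_subject Named integer vector `c(n_adl, n_fall)`.
#' @param fs Sampling rate (Hz).
#' @param adl_duration_s Range (s) of ADL trial durations.
#' @param pre_fall_s Range (s) of the quiet pre-fall phase of fall trials.
#' @param instability_s Range (s) of the instability phase preceding the
#'   descent; the annotated fall onset is its start.
#' @param fall_descent_ms Range (ms) of the descent (partial free-fall)
#'   phase ending at the impact frame.
#' @param wearing_offset_deg Range (deg) of the per-subject wearing offset
#'   magnitude on each axis (roll/pitch/yaw, random signs).
#' @param noise_sd Named vector `c(accel = , gyro = )`: sensor noise sd in
#'   g and deg/s.
#' @param seed Master seed; per-trial substreams are derived by counter.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 8,
                         trials_per_subject = c(n_adl = 5, n_fall = 4),
                         fs = 100, adl_duration_s = c(10, 20),
                         pre_fall_s = c(3, 6), instability_s = c(0.5, 0.9),
                         fall_descent_ms = c(300, 600),
                         wearing_offset_deg = c(0, 35),
                         noise_sd = c(accel = 0.015, gyro = 0.4), seed = 1) {
  structure(list(n_subjects = n_subjects,
                 trials_per_subject = trials_per_subject, fs = fs,
                 adl_duration_s = adl_duration_s, pre_fall_s = pre_fall_s,
                 instability_s = instability_s,
                 fall_descent_ms = fall_descent_ms,
                 wearing_offset_deg = wearing_offset_deg,
                 noise_sd = noise_sd, seed = seed),
            class = "synth_config")
}

# vectorized quaternion from Euler trajectories (radians), scalar first
quat_from_euler_vec <- function(roll, pitch, yaw) {
  cr <- cos(roll / 2); sr <- sin(roll / 2)
  cp <- cos(pitch / 2); sp <- sin(pitch / 2)
  cy <- cos(yaw / 2); sy <- sin(yaw / 2)
  cbind(cy * cp * cr + sy * sp * sr,
        cy * cp * sr - sy * sp * cr,
        cy * sp * cr + sy * cp * sr,
        sy * cp * cr - cy * sp * sr)
}

# rowwise Hamilton product of two T x 4 quaternion matrices
quat_mult_rows <- function(p, q) {
  cbind(p[, 1] * q[, 1] - p[, 2] * q[, 2] - p[, 3] * q[, 3] - p[, 4] * q[, 4],
        p[, 1] * q[, 2] + p[, 2] * q[, 1] + p[, 3] * q[, 4] - p[, 4] * q[, 3],
        p[, 1] * q[, 3] - p[, 2] * q[, 4] + p[, 3] * q[, 1] + p[, 4] * q[, 2],
        p[, 1] * q[, 4] + p[, 2] * q[, 3] - p[, 3] * q[, 2] + p[, 4] * q[, 1])
}

# rotate global vectors into the body frame: b = R(q)^T v, rowwise
rotate_to_body <- function(qm, v) {
  q0 <- qm[, 1]; q1 <- qm[, 2]; q2 <- qm[, 3]; q3 <- qm[, 4]
  R11 <- 1 - 2 * (q2^2 + q3^2); R12 <- 2 * (q1 * q2 - q0 * q3)
  R13 <- 2 * (q1 * q3 + q0 * q2)
  R21 <- 2 * (q1 * q2 + q0 * q3); R22 <- 1 - 2 * (q1^2 + q3^2)
  R23 <- 2 * (q2 * q3 - q0 * q1)
  R31 <- 2 * (q1 * q3 - q0 * q2); R32 <- 2 * (q2 * q3 + q0 * q1)
  R33 <- 1 - 2 * (q1^2 + q2^2)
  cbind(R11 * v[, 1] + R21 * v[, 2] + R31 * v[, 3],
        R12 * v[, 1] + R22 * v[, 2] + R32 * v[, 3],
        R13 * v[, 1] + R23 * v[, 2] + R33 * v[, 3])
}

# body-frame angular velocity (deg/s) consistent with a quaternion
# trajectory: q_{t+1} = q_t (x) exp(dt/2 * omega)
gyro_from_quats <- function(qm, dt) {
  T_ <- nrow(qm)
  if (T_ < 2) return(matrix(0, T_, 3))
  qc <- cbind(qm[, 1], -qm[, 2], -qm[, 3], -qm[, 4])
  qrel <- quat_mult_rows(qc[-T_, , drop = FALSE], qm[-1, , drop = FALSE])
  flip <- qrel[, 1] < 0
  qrel[flip, ] <- -qrel[flip, ]
  vn <- sqrt(rowSums(qrel[, 2:4, drop = FALSE]^2))
  ang <- 2 * atan2(vn, qrel[, 1])
  scale <- ifelse(vn > 1e-15, ang / vn, 2 / pmax(qrel[, 1], 1e-15))
  w <- qrel[, 2:4, drop = FALSE] * scale / dt * 180 / pi
  rbind(w, w[nrow(w), , drop = FALSE])
}

# assemble an imu_trial from motion Euler trajectories (radians), a global
# linear-acceleration component (T x 3, g), a constant wearing offset and
# sensor noise
traj_to_trial <- function(roll, pitch, yaw, a_lin, offset_deg, noise_sd, fs,
                          subject_id, activity_code, is_fall = FALSE,
                          onset_frame = NA, impact_frame = NA,
                          trial_id = NULL) {
  T_ <- length(roll)
  qm <- quat_from_euler_vec(roll, pitch, yaw)
  qoff <- quat_from_euler(offset_deg[1] * pi / 180, offset_deg[2] * pi / 180,
                          offset_deg[3] * pi / 180)
  qs <- quat_mult_rows(qm, matrix(qoff, T_, 4, byrow = TRUE))
  gvec <- cbind(a_lin[, 1], a_lin[, 2], 1 + a_lin[, 3])
  a_body <- rotate_to_body(qs, gvec) +
    matrix(stats::rnorm(T_ * 3, 0, noise_sd[["accel"]]), T_, 3)
  w_body <- gyro_from_quats(qs, 1 / fs) +
    matrix(stats::rnorm(T_ * 3, 0, noise_sd[["gyro"]]), T_, 3)
  tr <- imu_trial(cbind(a_body, w_body), subject_id, activity_code,
                  is_fall = is_fall, fs = fs, onset_frame = onset_frame,
                  impact_frame = impact_frame, trial_id = trial_id)
  attr(tr, "quaternions") <- qs  # ground-truth sensor orientation
  tr
}

runif1 <- function(rg) stats::runif(1, rg[1], rg[2])

# raised-cosine step from 0 to 1 over n samples
smoothstep <- function(n) (1 - cos(pi * seq(0, 1, length.out = n))) / 2

#' Generate a synthetic ADL trial
#'
#' Gravity-consistent activity signals: the accelerometer reads the
#' rotated specific force (gravity plus linear acceleration) in the
#' sensor frame, and the gyroscope is consistent with the orientation
#' derivative. Kinds: `"static"` (constant orientation), `"walk"`
#' (gait-frequency torso oscillation with vertical bobbing),
#' `"sit_stand"` (slow pitch transitions), `"jump"` (repeated partial
#' free-fall and landing bumps).
#'
#' @param kind Activity kind.
#' @param cfg A [synth_config()].
#' @param offset_deg Wearing offset `c(roll, pitch, yaw)` in degrees.
#' @param subject_id,trial_id Identifiers.
#' @param trial_seed Substream seed; when `NA` the current RNG state is
#'   used.
#' @return An [imu_trial()] without impact annotation; the ground-truth
#'   orientation is attached as `attr(, "quaternions")`.
#' @export
generate_adl_trial <- function(kind = c("static", "walk", "sit_stand", "jump"),
                               cfg = synth_config(), offset_deg = c(0, 0, 0),
                               subject_id = "S01", trial_id = NULL,
                               trial_seed = NA) {
  kind <- match.arg(kind)
  if (!is.na(trial_seed)) set.seed(trial_seed)
  fs <- cfg$fs
  T_ <- round(runif1(cfg$adl_duration_s) * fs)
  tt <- seq_len(T_) / fs
  d2r <- pi / 180
  roll <- pitch <- yaw <- numeric(T_)
  a_lin <- matrix(0, T_, 3)
  code <- c(static = "D01", walk = "D02", sit_stand = "D03", jump = "D04")[kind]
  if (kind == "walk") {
    f <- stats::runif(1, 1.6, 2.2)
    pitch <- d2r * (4 + 2 * sin(2 * pi * f * tt))
    roll <- d2r * 3 * sin(pi * f * tt + stats::runif(1, 0, 2 * pi))
    a_lin[, 3] <- 0.12 * sin(2 * pi * f * tt)
    a_lin[, 1] <- 0.05 * sin(2 * pi * f * tt + pi / 3)
    attr_gait <- f
  } else if (kind == "sit_stand") {
    period <- stats::runif(1, 4, 6)
    phase <- (tt %% period) / period
    pitch <- d2r * 30 * (1 - cos(2 * pi * phase)) / 2
    a_lin[, 3] <- 0.2 * sin(2 * pi * phase)
  } else if (kind == "jump") {
    gap <- stats::runif(1, 1.8, 2.5)
    k <- 0L
    while ((start <- round((0.5 + k * gap) * fs)) + 50 < T_) {
      push <- start:(start + 9)
      flight <- (start + 10):(start + 34)
      land <- (start + 35):(start + 42)
      a_lin[push, 3] <- a_lin[push, 3] + 0.6 * sin(pi * seq_along(push) / 10)
      a_lin[flight, 3] <- a_lin[flight, 3] - 0.55
      a_lin[land, 3] <- a_lin[land, 3] + 1.0 * sin(pi * seq_along(land) / 8)
      k <- k + 1L
    }
    roll <- d2r * 1.5 * sin(2 * pi * 0.8 * tt)
  }
  tr <- traj_to_trial(roll, pitch, yaw, a_lin, offset_deg, cfg$noise_sd, fs,
                      subject_id, code, trial_id = trial_id)
  if (kind == "walk") attr(tr, "gait_hz") <- attr_gait
  tr
}

# shared fall-motion construction so paired-orientation trials can reuse it
fall_motion <- function(direction, cfg) {
  fs <- cfg$fs
  d2r <- pi / 180
  n_pre <- round(runif1(cfg$pre_fall_s) * fs)
  n_ins <- round(runif1(cfg$instability_s) * fs)
  n_desc <- round(runif1(cfg$fall_descent_ms) / 1000 * fs)
  n_post <- round(0.5 * fs)
  T_ <- n_pre + n_ins + n_desc + n_post
  roll <- pitch <- yaw <- numeric(T_)
  a_lin <- matrix(0, T_, 3)
  # instability: growing oscillating tilt reaching theta0
  theta0 <- stats::runif(1, 8, 15)
  i_ins <- n_pre + seq_len(n_ins)
  grow <- seq(0, 1, length.out = n_ins)
  wob <- grow * theta0 * (0.7 + 0.3 * sin(2 * pi * 3 * seq_len(n_ins) / fs))
  # descent: tilt to near-horizontal plus a partial free-fall dip
  thetaf <- stats::runif(1, 70, 85)
  i_desc <- n_pre + n_ins + seq_len(n_desc)
  prog <- smoothstep(n_desc)
  tilt_desc <- theta0 + (thetaf - theta0) * prog
  dip <- stats::runif(1, 0.55, 0.8)
  axis_sign <- sample(c(-1, 1), 1)
  tilt <- numeric(T_)
  tilt[i_ins] <- wob
  tilt[i_desc] <- tilt_desc
  i_post <- (n_pre + n_ins + n_desc) + seq_len(n_post)
  tilt[i_post] <- thetaf
  if (direction == "forward") pitch <- d2r * tilt
  else if (direction == "backward") pitch <- -d2r * tilt
  else roll <- d2r * axis_sign * tilt
  a_lin[i_desc, 3] <- -dip * sin(pi * prog)
  # impact spike just after the annotated impact frame
  impact <- n_pre + n_ins + n_desc
  spk <- impact + seq_len(5)
  a_lin[spk, 3] <- a_lin[spk, 3] + 3.5 * exp(-(seq_len(5) - 1) / 1.5)
  list(roll = roll, pitch = pitch, yaw = yaw, a_lin = a_lin,
       onset = n_pre + 1L, impact = impact)
}

#' Generate a synthetic fall trial
#'
#' A quiet pre-fall phase, an instability phase (the annotated fall
#' onset), a descent in which the trunk rotates toward horizontal while
#' the specific-force magnitude dips toward partial free fall, the
#' annotated impact frame, and a high-magnitude spike placed after the
#' impact frame (so pre-impact truncation removes it).
#'
#' @param direction `"forward"`, `"backward"` or `"lateral"`.
#' @inheritParams generate_adl_trial
#' @return A fall [imu_trial()] with `onset_frame` and `impact_frame`.
#' @export
generate_fall_trial <- function(direction = c("forward", "backward", "lateral"),
                                cfg = synth_config(), offset_deg = c(0, 0, 0),
                                subject_id = "S01", trial_id = NULL,
                                trial_seed = NA) {
  direction <- match.arg(direction)
  if (!is.na(trial_seed)) set.seed(trial_seed)
  m <- fall_motion(direction, cfg)
  code <- c(forward = "F01", backward = "F02", lateral = "F03")[direction]
  traj_to_trial(m$roll, m$pitch, m$yaw, m$a_lin, offset_deg, cfg$noise_sd,
                cfg$fs, subject_id, code, is_fall = TRUE,
                onset_frame = m$onset, impact_frame = m$impact,
                trial_id = trial_id)
}

#' Generate one fall motion under two wearing orientations
#'
#' Emits two trials sharing the identical underlying motion and noise
#' seed but different constant wearing offsets, for orientation-invariance
#' checks of the global-frame transform.
#'
#' @param direction Fall direction.
#' @param cfg A [synth_config()].
#' @param offset_a,offset_b Wearing offsets `c(roll, pitch, yaw)` (deg).
#' @param trial_seed Substream seed shared by both trials.
#' @return List of two fall [imu_trial()] objects.
#' @export
generate_paired_fall <- function(direction = "forward", cfg = synth_config(),
                                 offset_a = c(0, 0, 0),
                                 offset_b = c(20, 15, 30), trial_seed = 1) {
  set.seed(trial_seed)
  m <- fall_motion(direction, cfg)
  mk <- function(off, id) {
    set.seed(trial_seed + 13L)  # same sensor-noise draws for both
    traj_to_trial(m$roll, m$pitch, m$yaw, m$a_lin, off, cfg$noise_sd, cfg$fs,
                  "SP", "F01", is_fall = TRUE, onset_frame = m$onset,
                  impact_frame = m$impact, trial_id = id)
  }
  list(a = mk(offset_a, "SP_F01_a"), b = mk(offset_b, "SP_F01_b"))
}

#' Generate a full synthetic dataset
#'
#' Per-subject constant wearing offsets are drawn once and applied to all
#' of that subject's trials; ADL kinds and fall directions cycle through
#' their catalogs. Fully reproducible: all randomness derives from
#' `cfg$seed` with per-trial substreams indexed by counter.
#'
#' @param cfg A [synth_config()].
#' @return A list with `trials` (list of [imu_trial()]) and `manifest`
#'   (data frame of per-trial annotations).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  n_adl <- cfg$trials_per_subject[["n_adl"]]
  n_fall <- cfg$trials_per_subject[["n_fall"]]
  kinds <- rep(c("walk", "static", "sit_stand", "jump"), length.out = n_adl)
  dirs <- rep(c("forward", "backward", "lateral"), length.out = n_fall)
  trials <- list()
  rows <- list()
  counter <- 0L
  for (si in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", si)
    set.seed((cfg$seed + 104729L * si) %% .Machine$integer.max)
    mag <- stats::runif(3, cfg$wearing_offset_deg[1], cfg$wearing_offset_deg[2])
    off <- mag * sample(c(-1, 1), 3, replace = TRUE)
    for (j in seq_len(n_adl)) {
      counter <- counter + 1L
      id <- sprintf("%s_%s_T%02d", sid, kinds[j], j)
      tr <- generate_adl_trial(kinds[j], cfg, off, sid, trial_id = id,
                               trial_seed = (cfg$seed + 7919L * counter) %%
                                 .Machine$integer.max)
      trials[[id]] <- tr
      rows[[id]] <- data.frame(trial_id = id, subject = sid,
                               activity = tr$activity_code, is_fall = FALSE,
                               n_samples = nrow(tr$samples),
                               onset_frame = NA_integer_,
                               impact_frame = NA_integer_)
    }
    for (j in seq_len(n_fall)) {
      counter <- counter + 1L
      id <- sprintf("%s_%s_T%02d", sid, dirs[j], n_adl + j)
      tr <- generate_fall_trial(dirs[j], cfg, off, sid, trial_id = id,
                                trial_seed = (cfg$seed + 7919L * counter) %%
                                  .Machine$integer.max)
      trials[[id]] <- tr
      rows[[id]] <- data.frame(trial_id = id, subject = sid,
                               activity = tr$activity_code, is_fall = TRUE,
                               n_samples = nrow(tr$samples),
                               onset_frame = tr$onset_frame,
                               impact_frame = tr$impact_frame)
    }
  }
  list(trials = unname(trials), manifest = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
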