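#' Attitude filter configuration
#'
#' Gains and constants of the Madgwick gradient-descent attitude filter.
#'
#' @param beta Accelerometer-correction gain (dimensionless). Controls how
#'   strongly the normalized gradient step pulls the quaternion toward the
#'   measured gravity direction; default 0.1.
#' @param epsilon Free-fall gating threshold on the acceleration magnitude,
#'   in g. When `||a|| <= epsilon` the gravity direction is unobservable and
#'   the filter falls back to the gyroscope-only update; default 0.1 g.
#' @param dt Sample period in seconds; default 0.01 (100 Hz).
#' @return A list of class `madgwick_config`.
#' @export
madgwick_config <- function(beta = 0.1, epsilon = 0.1, dt = 0.01) {
  stopifnot(beta >= 0, epsilon > 0, dt > 0)  # beta = 0: gyro-only integration
  structure(list(beta = beta, epsilon = epsilon, dt = dt,
                 gravity_ref = c(0, 0, 1)),
            class = "madgwick_config")
}

#' One Madgwick filter update
#'
#' Advances the attitude quaternion by one sample: gyroscope-driven
#' quaternion rate, accelerometer gradient-descent correction along the
#' normalized objective gradient (taken only when `||a||` exceeds the
#' free-fall gate), first-order Euler integration and renormalization.
#'
#' @param q Current unit quaternion (scalar first).
#' @param a Accelerometer sample, 3-vector in g.
#' @param w Gyroscope sample, 3-vector in deg/s (converted internally).
#' @param cfg A [madgwick_config()].
#' @return The updated unit quaternion.
#' @export
madgwick_step <- function(q, a, w, cfg = madgwick_config()) {
  wr <- w * pi / 180
  qdot <- 0.5 * quat_multiply(q, c(0, wr))
  an <- sqrt(sum(a^2))
  if (an > cfg$epsilon) {
    ah <- a / an
    f <- c(2 * (q[2] * q[4] - q[1] * q[3]) - ah[1],
           2 * (q[1] * q[2] + q[3] * q[4]) - ah[2],
           2 * (0.5 - q[2]^2 - q[3]^2) - ah[3])
    J <- matrix(c(-2 * q[3], 2 * q[4], -2 * q[1], 2 * q[2],
                   2 * q[2], 2 * q[1],  2 * q[4], 2 * q[3],
                   0,       -4 * q[2], -4 * q[3], 0),
                nrow = 3, byrow = TRUE)
    grad <- drop(crossprod(J, f))
    gn <- sqrt(sum(grad^2))
    # guard: a vanishing gradient (already at the objective minimum, or a
    # degenerate attitude) reduces to the gyroscope-only update
    if (gn > 1e-12) qdot <- qdot - cfg$beta * grad / gn
  }
  quat_normalize(q + qdot * cfg$dt)
}

#' Transform an inertial sequence into the gravity-aligned global frame
#'
#' Runs the Madgwick filter over a body-frame recording (fresh identity
#' initialization at the sequence start) and rotates every sample into the
#' global frame with the per-sample rotation matrix. Rotation preserves the
#' per-sample norms of both signals.
#'
#' @param a_body T x 3 accelerometer matrix in g.
#' @param w_body T x 3 gyroscope matrix in deg/s.
#' @param cfg A [madgwick_config()].
#' @return An object of class `dual_frame`: a list with `a_body`, `w_body`,
#'   `a_global`, `w_global` (all T x 3) and `quaternions` (T x 4), plus the
#'   configuration used.
#' @export
madgwick_transform <- function(a_body, w_body, cfg = madgwick_config()) {
  a_body <- as.matrix(a_body); w_body <- as.matrix(w_body)
  stopifnot(ncol(a_body) == 3, ncol(w_body) == 3)
  if (nrow(a_body) != nrow(w_body))
    stop("accelerometer and gyroscope streams must have equal length")
  bad <- which(!is.finite(a_body)) ; badw <- which(!is.finite(w_body))
  if (length(bad) || length(badw)) {
    idx <- sort(unique(c((bad - 1) %% nrow(a_body) + 1,
                         (badw - 1) %% nrow(w_body) + 1)))
    stop("non-finite samples at index ", paste(utils::head(idx, 5), collapse = ", "))
  }
  T_ <- nrow(a_body)
  q <- c(1, 0, 0, 0)
  a_global <- matrix(0, T_, 3); w_global <- matrix(0, T_, 3)
  quats <- matrix(0, T_, 4)
  for (t in seq_len(T_)) {
    q <- madgwick_step(q, a_body[t, ], w_body[t, ], cfg)
    R <- quat_to_rotmat(q, tol = 1e-6)
    a_global[t, ] <- R %*% a_body[t, ]
    w_global[t, ] <- R %*% w_body[t, ]
    quats[t, ] <- q
  }
  structure(list(a_body = a_body, w_body = w_body,
                 a_global = a_global, w_global = w_global,
                 quaternions = quats, cfg = cfg),
            class = "dual_frame")
}

#' @export
print.dual_frame <- function(x, ...) {
  cat("Dual-frame inertial sequence:", nrow(x$a_body), "samples at dt =",
      x$cfg$dt, "s\n")
  invisible(x)
}

#' Detect gravity-alignment convergence of a transformed sequence
#'
#' Finds the earliest time at which the angular deviation of the global
#' acceleration from the vertical stays below `angle_tol_deg` for
#' `hold_s` consecutive seconds. Intended for static or quasi-static
#' streams (warm-up assessment).
#'
#' @param seq A `dual_frame` object from [madgwick_transform()].
#' @param angle_tol_deg Angular tolerance in degrees (default 5).
#' @param hold_s Required hold duration in seconds (default 0.5).
#' @return Convergence time in seconds (time of the end of the first full
#'   hold window), or `NA` if the criterion never holds.
#' @export
detect_convergence <- function(seq, angle_tol_deg = 5, hold_s = 0.5) {
  stopifnot(inherits(seq, "dual_frame"))
  dt <- seq$cfg$dt
  hold_n <- round(hold_s / dt)
  ag <- seq$a_global
  if (nrow(ag) < hold_n)
    stop("sequence shorter than the hold window (", hold_n, " samples)")
  nrm <- sqrt(rowSums(ag^2))
  cosang <- ifelse(nrm > 0, pmin(1, pmax(-1, ag[, 3] / nrm)), -1)
  ok <- acos(cosang) * 180 / pi < angle_tol_deg
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= hold_n)
  if (!length(hit)) return(NA_real_)
  (starts[hit[1]] + hold_n - 1) * dt
}
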