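#' Augmentation configuration
#'
#' Parameters for the training-set-only fall-window augmentation: additive
#' Gaussian jitter (sigma 0.04), global scaling drawn from N(1.0, 0.10^2)
#' (one factor per window copy), and smooth spline time warping
#' (sigma 0.15, 4 interior knots). Seven augmented copies per fall window
#' by default; `N(1.0, 0.10)` is read as a standard deviation of 0.10.
#'
#' @param jitter_sigma Jitter standard deviation (g / deg-per-s units of
#'   the channel it is added to).
#' @param scale_mean,scale_sd Mean and sd of the scaling factor.
#' @param warp_sigma Sd of the warp knot magnitudes around 1.
#' @param warp_knots Number of interior warp knots (>= 2).
#' @param n_copies Augmented copies per fall window (>= 0).
#' @param seed RNG seed used by [augment_falls()].
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(jitter_sigma = 0.04, scale_mean = 1.0,
                           scale_sd = 0.10, warp_sigma = 0.15, warp_knots = 4,
                           n_copies = 7, seed = 42) {
  stopifnot(n_copies >= 0, warp_knots >= 2)
  structure(list(jitter_sigma = jitter_sigma, scale_mean = scale_mean,
                 scale_sd = scale_sd, warp_sigma = warp_sigma,
                 warp_knots = warp_knots, n_copies = n_copies, seed = seed),
            class = "augment_config")
}

#' Additive Gaussian jitter
#'
#' Adds elementwise N(0, sigma^2) noise; shape preserved. Draws from the
#' current RNG state.
#'
#' @param w Numeric matrix or array (a window stream, e.g. 3 x 87).
#' @param sigma Noise standard deviation.
#' @return Jittered window of the same shape.
#' @export
jitter_window <- function(w, sigma) {
  if (sigma == 0) return(w)
  w + array(stats::rnorm(length(w), 0, sigma), dim = dim(w) %||% length(w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random global scaling
#'
#' Draws one scalar factor from N(mean, sd^2) and multiplies the whole
#' window by it (one factor per window, all channels alike, mimicking
#' body-size variation).
#'
#' @param w Numeric matrix/array, or a list of streams scaled jointly.
#' @param mean,sd Scaling-factor distribution parameters.
#' @return Scaled window; the drawn factor is attached as
#'   `attr(, "factor")`.
#' @export
scale_window <- function(w, mean = 1.0, sd = 0.10) {
  f <- if (sd == 0) mean else stats::rnorm(1, mean, sd)
  out <- if (is.list(w)) lapply(w, function(m) m * f) else w * f
  attr(out, "factor") <- f
  out
}

# internal: draw a monotone cumulative warp of length T mapping [1, T] onto
# itself; knot magnitudes ~ N(1, sigma^2) through a cubic spline.
draw_time_warp <- function(n, sigma, knots) {
  for (attempt in 1:20) {
    kx <- seq(1, n, length.out = knots + 2)
    ky <- stats::rnorm(knots + 2, 1, sigma)
    ky <- pmax(ky, 0.05)  # clip to keep increments positive
    speed <- stats::spline(kx, ky, n = n)$y
    if (any(speed <= 0)) { message("non-monotone warp, resampling"); next }
    cum <- cumsum(speed)
    # endpoints fixed: map to [1, n] exactly
    return(1 + (cum - cum[1]) / (cum[n] - cum[1]) * (n - 1))
  }
  stop("failed to draw a monotone time warp")
}

#' Smooth spline time warping
#'
#' Builds a smooth monotone time remapping from a cubic spline through
#' `knots` interior knots with N(1, sigma^2) magnitudes, endpoints fixed,
#' and linearly re-interpolates the window to its original length. The
#' same warp is applied to every channel (and to every stream when `w` is
#' a list), preserving cross-stream timing.
#'
#' @param w A channels x T matrix, or a list of such matrices warped with
#'   one shared warp.
#' @param sigma Knot-magnitude standard deviation.
#' @param knots Number of interior knots.
#' @return Warped window of identical shape.
#' @export
time_warp_window <- function(w, sigma = 0.15, knots = 4) {
  n <- if (is.list(w)) ncol(w[[1]]) else ncol(w)
  if (n < knots + 2) stop("window too short for ", knots, " warp knots")
  warped_t <- if (sigma == 0) seq_len(n) else draw_time_warp(n, sigma, knots)
  warp1 <- function(m) {
    out <- m
    for (ch in seq_len(nrow(m)))
      out[ch, ] <- stats::approx(seq_len(n), m[ch, ], xout = warped_t,
                                 rule = 2)$y
    out
  }
  if (is.list(w)) lapply(w, warp1) else warp1(w)
}

#' Augment the fall windows of a training window set
#'
#' Each label-1 window yields `n_copies` augmented variants (the original
#' is retained), every variant applying jitter, scaling and time warping
#' in sequence with independent draws. Jitter is drawn independently per
#' stream; the scale factor and the warp are shared across the four
#' streams of a window. ADL windows are untouched. Refuses to run on a
#' window set flagged as test data (leakage guard).
#'
#' @param ws A `window_set` (training fold).
#' @param cfg An [augment_config()].
#' @return The augmented `window_set`.
#' @export
augment_falls <- function(ws, cfg = augment_config()) {
  stopifnot(inherits(ws, "window_set"))
  role <- attr(ws, "role")
  if (!is.null(role) && identical(role, "test"))
    stop("augment_falls() refuses test-flagged windows: augmentation is train-only")
  idx <- which(ws$label == 1L)
  if (!length(idx) || cfg$n_copies == 0) return(ws)
  set.seed(cfg$seed)
  n_win <- attr(ws, "n_win")
  n_new <- length(idx) * cfg$n_copies
  add <- new_window_set(n_win)
  add$x <- lapply(add$x, function(a) array(0, c(3, n_win, n_new)))
  j <- 0L
  for (i in idx) {
    streams <- lapply(ws$x, function(a) a[, , i])
    for (cp in seq_len(cfg$n_copies)) {
      j <- j + 1L
      v <- lapply(streams, jitter_window, sigma = cfg$jitter_sigma)
      v <- scale_window(v, cfg$scale_mean, cfg$scale_sd)
      v <- time_warp_window(v, cfg$warp_sigma, cfg$warp_knots)
      for (s in names(add$x)) add$x[[s]][, , j] <- v[[s]]
    }
  }
  rep_i <- rep(idx, each = cfg$n_copies)
  add$label <- rep(1L, n_new)
  add$trial_id <- ws$trial_id[rep_i]
  add$subject <- ws$subject[rep_i]
  add$activity <- ws$activity[rep_i]
  add$end_index <- ws$end_index[rep_i]
  out <- ws_bind(ws, add)
  attr(out, "role") <- role
  attr(out, "n_win") <- n_win
  out
}
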