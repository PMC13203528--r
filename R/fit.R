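#' Training configuration
#'
#' The fixed optimization recipe: AdamW with decoupled weight decay,
#' cosine-annealing learning-rate schedule with warm restarts (stepped per
#' epoch), class-weighted cross-entropy with label smoothing, batch size
#' 64, gradient clipping at a global l2 norm of 0.8, seed 42.
#'
#' @param lr Initial learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param t0 Epochs of the first cosine cycle.
#' @param t_mult Cycle-length multiplier at each restart.
#' @param eta_min Learning-rate floor.
#' @param label_smoothing Smoothing coefficient of the loss.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param grad_clip Maximum global l2 gradient norm.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param bn_momentum Running-statistics momentum of the normalization
#'   layers.
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 0.001, weight_decay = 8e-5, t0 = 15, t_mult = 2,
                         eta_min = 1e-6, label_smoothing = 0.01,
                         batch_size = 64, epochs = 105, grad_clip = 0.8,
                         seed = 42, bn_momentum = 0.1) {
  structure(list(lr = lr, weight_decay = weight_decay, t0 = t0,
                 t_mult = t_mult, eta_min = eta_min,
                 label_smoothing = label_smoothing, batch_size = batch_size,
                 epochs = epochs, grad_clip = grad_clip, seed = seed,
                 bn_momentum = bn_momentum),
            class = "train_config")
}

#' Cosine-annealing learning rate with warm restarts
#'
#' Learning rate of a 1-based epoch under per-epoch stepping. Cycle `j`
#' lasts `t0 * t_mult^(j-1)` epochs; within a cycle of length `Ti`, epoch
#' offset `tc` (0-based) gives
#' `eta_min + (lr - eta_min) * (1 + cos(pi * tc / Ti)) / 2`.
#'
#' @param epoch 1-based epoch number (vectorized).
#' @param cfg A [train_config()].
#' @return Learning rate(s).
#' @export
cosine_restart_lr <- function(epoch, cfg = train_config()) {
  vapply(epoch, function(e) {
    tc <- e - 1
    ti <- cfg$t0
    while (tc >= ti) { tc <- tc - ti; ti <- ti * cfg$t_mult }
    cfg$eta_min + (cfg$lr - cfg$eta_min) * (1 + cos(pi * tc / ti)) / 2
  }, numeric(1))
}

#' Warm-restart epochs of the schedule
#'
#' @param cfg A [train_config()].
#' @param n_restarts How many restarts to list.
#' @return 1-based epochs at which a new cosine cycle begins (the first
#'   cycle starts at epoch 1 and is not counted as a restart).
#' @export
restart_epochs <- function(cfg = train_config(), n_restarts = 3) {
  out <- numeric(n_restarts)
  e <- 0; ti <- cfg$t0
  for (i in seq_len(n_restarts)) { e <- e + ti; out[i] <- e; ti <- ti * cfg$t_mult }
  out
}

#' Inverse-frequency class weights
#'
#' Weights each class by the inverse of its empirical frequency,
#' normalized to mean 1 over the two classes.
#'
#' @param labels Integer vector of 0/1 labels; both classes must occur.
#' @return Numeric 2-vector `c(w0, w1)`.
#' @export
class_weights <- function(labels) {
  n <- c(sum(labels == 0), sum(labels == 1))
  if (any(n == 0)) stop("both classes must be present to compute class weights")
  w <- (sum(n) / n)
  w / mean(w)
}

# ---- flat parameter traversal (optimizer bookkeeping) ----

flatten_leaves <- function(x) {
  if (!is.list(x)) return(list(x))
  do.call(c, lapply(x, flatten_leaves))
}

# reorder a gradient list to the exact leaf order of the parameter list
align_grads <- function(params, grads) {
  list(branches = lapply(seq_along(params$branches), function(i)
         grads$branches[[i]][names(params$branches[[i]])]),
       head = grads$head[names(params$head)])
}

relist_like <- function(flat, skeleton) {
  i <- 0L
  rebuild <- function(x) {
    if (!is.list(x)) { i <<- i + 1L; return(flat[[i]]) }
    out <- lapply(x, rebuild)
    attributes(out) <- attributes(x)
    out
  }
  rebuild(skeleton)
}

#' Fit the dual-frame fall classifier
#'
#' Trains the network on windowed dual-frame inertial data with the fixed
#' recipe of [train_config()]: AdamW, cosine warm restarts stepped per
#' epoch, class-weighted smoothed cross-entropy, global-norm gradient
#' clipping. All randomness (initialization, shuffling, dropout) flows
#' from `control$seed`. The final-epoch parameters are returned (no early
#' stopping or model selection).
#'
#' @param x A `window_set` or a named list of stream arrays
#'   (`ba`, `bg`, `ga`, `gg`; each 3 x T x N).
#' @param y Integer 0/1 labels; taken from the window set when missing.
#' @param spec A [fallnet_spec()].
#' @param control A [train_config()].
#' @param class_wt Optional 2-vector of class weights; computed by
#'   [class_weights()] from `y` when `NULL`.
#' @param verbose Print per-epoch loss.
#' @return An object of class `fallnet` with elements `net` (parameters,
#'   state, spec), `control`, `history` (per-epoch data frame), and
#'   `class_wt`.
#' @export
fallnet_fit <- function(x, y = NULL, spec = fallnet_spec(),
                        control = train_config(), class_wt = NULL,
                        verbose = FALSE) {
  if (inherits(x, "window_set")) {
    if (is.null(y)) y <- x$label
    x <- x$x
  }
  if (is.null(y)) stop("labels 'y' are required")
  xs_all <- lapply(spec$streams, function(s) {
    if (is.null(x[[s]])) stop("missing input stream '", s, "'")
    x[[s]]
  })
  n <- dim(xs_all[[1]])[3]
  stopifnot(length(y) == n, n >= 2)
  y <- as.integer(y)
  if (is.null(class_wt)) class_wt <- class_weights(y)

  set.seed(control$seed)
  net <- fallnet_init(spec)
  params <- net$params
  state <- net$state
  skel <- params
  flat <- flatten_leaves(params)
  m <- lapply(flat, function(p) p * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  tstep <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))

  for (epoch in seq_len(control$epochs)) {
    lr <- cosine_restart_lr(epoch, control)
    ord <- sample.int(n)
    nb <- max(1L, floor(n / control$batch_size))
    bounds <- floor(seq(0, n, length.out = nb + 1))
    ep_loss <- 0; ep_n <- 0
    for (bi in seq_len(nb)) {
      ids <- ord[(bounds[bi] + 1):bounds[bi + 1]]
      xb <- lapply(xs_all, function(a) a[, , ids, drop = FALSE])
      res <- cpp_fallnet_loss_grad(params, state, xb, y[ids], class_wt,
                                   control$label_smoothing, spec$tcn_dropout,
                                   spec$fc_dropout, spec$gn_groups,
                                   control$bn_momentum)
      state <- res$state
      g <- flatten_leaves(align_grads(params, res$grads))
      gn <- sqrt(sum(vapply(g, function(gi) sum(gi^2), numeric(1))))
      if (is.finite(gn) && gn > control$grad_clip)
        g <- lapply(g, function(gi) gi * (control$grad_clip / gn))
      if (!is.finite(res$loss))
        stop("non-finite loss at epoch ", epoch, ", batch ", bi)
      tstep <- tstep + 1L
      flat <- flatten_leaves(params)
      c1 <- 1 - b1^tstep; c2 <- 1 - b2^tstep
      for (i in seq_along(flat)) {
        m[[i]] <- b1 * m[[i]] + (1 - b1) * g[[i]]
        v[[i]] <- b2 * v[[i]] + (1 - b2) * g[[i]]^2
        upd <- (m[[i]] / c1) / (sqrt(v[[i]] / c2) + eps) +
          control$weight_decay * flat[[i]]
        flat[[i]] <- flat[[i]] - lr * upd
      }
      params <- relist_like(flat, skel)
      ep_loss <- ep_loss + res$loss * length(ids)
      ep_n <- ep_n + length(ids)
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = ep_loss / ep_n, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  lr %.2e", epoch, ep_loss / ep_n, lr))
  }
  net$params <- params
  net$state <- state
  structure(list(net = net, control = control, history = history,
                 class_wt = class_wt, n_train = n),
            class = "fallnet")
}

#' @export
print.fallnet <- function(x, ...) {
  cp <- count_parameters(x)
  cat(sprintf(
    "Dual-frame fall classifier: %d branch(es) [%s], %d parameters (%.1f KB fp16)\n",
    length(x$net$spec$streams), paste(x$net$spec$streams, collapse = ","),
    cp$n_params, cp$fp16_kb))
  cat(sprintf("Trained %d epochs on %d windows; final loss %.4f\n",
              nrow(x$history), x$n_train, x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.fallnet <- function(object, ...) {
  cp <- count_parameters(object)
  out <- list(spec = object$net$spec, n_params = cp$n_params,
              fp16_kb = cp$fp16_kb, control = object$control,
              history = object$history, class_wt = object$class_wt)
  class(out) <- "summary.fallnet"
  out
}

#' @export
print.summary.fallnet <- function(x, ...) {
  print(x$spec)
  cat(sprintf("parameters: %d (%.1f KB fp16); class weights %.3f/%.3f\n",
              x$n_params, x$fp16_kb, x$class_wt[1], x$class_wt[2]))
  cat(sprintf("epochs: %d, final loss %.4f (initial %.4f)\n",
              nrow(x$history), x$history$loss[nrow(x$history)],
              x$history$loss[1]))
  invisible(x)
}

#' @export
coef.fallnet <- function(object, ...) {
  flat <- flatten_leaves(object$net$params)
  unlist(flat, use.names = FALSE)
}

#' Predict fall probabilities or classes
#'
#' Inference-mode forward pass (dropout off, normalization using running
#' statistics). A window is called a fall when its probability exceeds
#' 0.5.
#'
#' @param object A fitted `fallnet`.
#' @param newdata A `window_set` or named list of stream arrays.
#' @param type `"prob"` (fall probability), `"class"` (0/1 decision at
#'   the 0.5 threshold) or `"matrix"` (both class probabilities).
#' @param ... Ignored.
#' @return Numeric vector (or 2-column matrix for `type = "matrix"`).
#' @export
predict.fallnet <- function(object, newdata,
                            type = c("prob", "class", "matrix"), ...) {
  type <- match.arg(type)
  net <- object$net
  if (inherits(newdata, "window_set")) newdata <- newdata$x
  xs <- lapply(net$spec$streams, function(s) newdata[[s]])
  # chunk inference to bound memory on large window sets
  n <- dim(xs[[1]])[3]
  probs <- numeric(n)
  chunk <- 512L
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    xb <- lapply(xs, function(a) a[, , lo:hi, drop = FALSE])
    p <- cpp_fallnet_forward(net$params, net$state, xb, net$spec$gn_groups)
    probs[lo:hi] <- p[2, ]
  }
  switch(type,
         prob = probs,
         class = as.integer(probs > 0.5),
         matrix = cbind(adl = 1 - probs, fall = probs))
}

#' @export
plot.fallnet <- function(x, ...) {
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = "Training loss", ...)
  invisible(x)
}
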