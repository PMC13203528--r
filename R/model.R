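#' Architectural hyperparameters of the four-branch classifier
#'
#' Describes every architectural choice of the dual-frame network: two
#' DS-SE blocks (depthwise-separable temporal convolution with
#' squeeze-and-excitation attention) per branch, a max-pool between them,
#' a two-block causal dilated TCN, group normalization and global average
#' pooling into a 32-dimensional branch feature; features from all
#' branches are concatenated and classified by a two-layer head.
#'
#' @param streams Character vector naming the input streams consumed, in
#'   order, among `"ba"`, `"bg"`, `"ga"`, `"gg"` (body/global x
#'   accel/gyro). The default uses all four; two-stream subsets give the
#'   reduced body-only / global-only ablation variants.
#' @param in_channels Input channels per stream (3 axes).
#' @param t_steps Samples per window (87).
#' @param c1,k1 Output channels and kernel length of the first DS-SE block.
#' @param c2,k2 Output channels and kernel length of the second DS-SE block.
#' @param se_reduction SE channel-reduction ratio r; hidden width is
#'   `floor(C/r)`, at least 1.
#' @param se_bias Logical; include bias vectors in the SE fully connected
#'   layers (standard SE form).
#' @param tcn_channels,tcn_kernel TCN width and kernel length.
#' @param tcn_layers Number of temporal blocks; dilation of block i is 2^(i-1).
#' @param tcn_dropout Dropout probability inside the temporal blocks.
#' @param gn_groups Groups of the group-normalization layer.
#' @param fc_hidden Width of the classifier hidden layer.
#' @param fc_dropout Classifier dropout probability.
#' @param n_classes Output classes (2: ADL vs fall).
#' @return A list of class `fallnet_spec`.
#' @export
fallnet_spec <- function(streams = c("ba", "bg", "ga", "gg"), in_channels = 3,
                         t_steps = 87, c1 = 16, k1 = 9, c2 = 32, k2 = 7,
                         se_reduction = 6, se_bias = TRUE, tcn_channels = 32,
                         tcn_kernel = 3, tcn_layers = 2, tcn_dropout = 0.08,
                         gn_groups = 4, fc_hidden = 48, fc_dropout = 0.30,
                         n_classes = 2) {
  streams <- match.arg(streams, c("ba", "bg", "ga", "gg"), several.ok = TRUE)
  if (!length(streams)) stop("at least one input stream is required")
  stopifnot(tcn_layers == 2,  # dilations 1 and 2, receptive field 13
            tcn_channels %% gn_groups == 0, c2 == tcn_channels,
            k1 %% 2 == 1, k2 %% 2 == 1)
  structure(list(streams = streams, in_channels = in_channels,
                 t_steps = t_steps, c1 = c1, k1 = k1, c2 = c2, k2 = k2,
                 se_reduction = se_reduction, se_bias = se_bias,
                 tcn_channels = tcn_channels, tcn_kernel = tcn_kernel,
                 tcn_layers = tcn_layers, tcn_dropout = tcn_dropout,
                 gn_groups = gn_groups, fc_hidden = fc_hidden,
                 fc_dropout = fc_dropout, n_classes = n_classes,
                 branch_feature_dim = tcn_channels,
                 fused_dim = length(streams) * tcn_channels),
            class = "fallnet_spec")
}

#' @export
print.fallnet_spec <- function(x, ...) {
  cat(sprintf(
    "fallnet spec: %d branch(es) [%s], DS-SE (%d,%d,k=%d) -> pool -> (%d,%d,k=%d),\n  TCN %d ch k=%d x%d blocks, SE r=%d, fused dim %d, head %d->%d->%d\n",
    length(x$streams), paste(x$streams, collapse = ","), x$in_channels, x$c1,
    x$k1, x$c1, x$c2, x$k2, x$tcn_channels, x$tcn_kernel, x$tcn_layers,
    x$se_reduction, x$fused_dim, x$fused_dim, x$fc_hidden, x$n_classes))
  invisible(x)
}

# He-style initial weights; all draws through R's RNG for reproducibility
rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

se_hidden <- function(C, r) max(1L, C %/% r)

# parameters of one DS-SE block, prefixed (convolutions are bias-free)
dsse_params <- function(prefix, c_in, c_out, k, r, se_bias) {
  h <- se_hidden(c_out, r)
  p <- list(
    dw = rmat(c_in, k, sqrt(2 / k)),
    pw = rmat(c_out, c_in, sqrt(2 / c_in)),
    bng = rep(1, c_out), bnb = rep(0, c_out),
    se_W1 = rmat(h, c_out, sqrt(2 / c_out)),
    se_W2 = rmat(c_out, h, sqrt(2 / h)))
  if (se_bias) { p$se_b1 <- rep(0, h); p$se_b2 <- rep(0, c_out) }
  names(p) <- paste(prefix, names(p), sep = "_")
  p
}

ltb_params <- function(prefix, ch, k) {
  p <- list(dw1 = rmat(ch, k, sqrt(2 / k)), pw1 = rmat(ch, ch, sqrt(2 / ch)),
            bn1g = rep(1, ch), bn1b = rep(0, ch),
            dw2 = rmat(ch, k, sqrt(2 / k)), pw2 = rmat(ch, ch, sqrt(2 / ch)),
            bn2g = rep(1, ch), bn2b = rep(0, ch))
  names(p) <- paste(prefix, names(p), sep = "_")
  p
}

branch_params <- function(spec) {
  c(dsse_params("d1", spec$in_channels, spec$c1, spec$k1, spec$se_reduction,
                spec$se_bias),
    dsse_params("d2", spec$c1, spec$c2, spec$k2, spec$se_reduction,
                spec$se_bias),
    ltb_params("l1", spec$tcn_channels, spec$tcn_kernel),
    ltb_params("l2", spec$tcn_channels, spec$tcn_kernel),
    list(gn_g = rep(1, spec$tcn_channels), gn_b = rep(0, spec$tcn_channels)))
}

branch_state <- function(spec) {
  zs <- function(n) rep(0, n); os <- function(n) rep(1, n)
  list(d1_rm = zs(spec$c1), d1_rv = os(spec$c1),
       d2_rm = zs(spec$c2), d2_rv = os(spec$c2),
       l1_bn1_rm = zs(spec$tcn_channels), l1_bn1_rv = os(spec$tcn_channels),
       l1_bn2_rm = zs(spec$tcn_channels), l1_bn2_rv = os(spec$tcn_channels),
       l2_bn1_rm = zs(spec$tcn_channels), l2_bn1_rv = os(spec$tcn_channels),
       l2_bn2_rm = zs(spec$tcn_channels), l2_bn2_rv = os(spec$tcn_channels))
}

#' Initialize network parameters
#'
#' Builds the trainable parameters and the normalization state of the
#' network described by a [fallnet_spec()]. Branches share structure but
#' have independent parameters. Draws initial weights from the current
#' RNG state.
#'
#' @param spec A [fallnet_spec()].
#' @return A list of class `fallnet_params` with elements `params`
#'   (nested list: `branches`, `head`), `state` (normalization running
#'   statistics) and `spec`.
#' @export
fallnet_init <- function(spec = fallnet_spec()) {
  nb <- length(spec$streams)
  branches <- lapply(seq_len(nb), function(i) branch_params(spec))
  fused <- spec$fused_dim
  head <- list(
    fc1_W = rmat(spec$fc_hidden, fused, sqrt(2 / fused)),
    fc1_b = rep(0, spec$fc_hidden),
    bn_g = rep(1, spec$fc_hidden), bn_b = rep(0, spec$fc_hidden),
    fc2_W = rmat(spec$n_classes, spec$fc_hidden, sqrt(1 / spec$fc_hidden)),
    fc2_b = rep(0, spec$n_classes))
  structure(list(
    params = list(branches = branches, head = head),
    state = list(branches = lapply(seq_len(nb), function(i) branch_state(spec)),
                 head = list(bn_rm = rep(0, spec$fc_hidden),
                             bn_rv = rep(1, spec$fc_hidden))),
    spec = spec), class = "fallnet_params")
}

# extract the params/state/spec triple from a fallnet or fallnet_params
as_net <- function(object) {
  if (inherits(object, "fallnet")) object$net
  else if (inherits(object, "fallnet_params")) object
  else stop("expected a 'fallnet' or 'fallnet_params' object")
}

#' Count trainable parameters and half-precision size
#'
#' Counts every trainable scalar of the built network (normalization
#' running statistics are state, not parameters) and reports the size of
#' an FP16 export at 2 bytes per parameter.
#'
#' @param object A `fallnet` model or `fallnet_params` object.
#' @return A list with `n_params` and `fp16_kb` (`2 * n_params / 1024`).
#' @export
count_parameters <- function(object) {
  net <- as_net(object)
  n <- sum(unlist(rapply(net$params, length, how = "unlist")))
  list(n_params = as.integer(n), fp16_kb = 2 * n / 1024)
}

#' Convolution-weight compression ratio of a DS-SE block
#'
#' Computes, from the built block's parameter tensors, the ratio between
#' the weight count of a standard convolution (`c_in * c_out * k`) and the
#' depthwise-separable weight count actually instantiated
#' (`c_in * k + c_in * c_out`).
#'
#' @param object A `fallnet` or `fallnet_params` object.
#' @param block Which DS-SE block, 1 or 2.
#' @return The compression ratio (fold).
#' @export
dsse_compression_ratio <- function(object, block = 1) {
  net <- as_net(object)
  pre <- paste0("d", block)
  bp <- net$params$branches[[1]]
  dw <- bp[[paste0(pre, "_dw")]]
  pw <- bp[[paste0(pre, "_pw")]]
  c_in <- nrow(dw); k <- ncol(dw); c_out <- nrow(pw)
  (c_in * c_out * k) / (length(dw) + length(pw))
}

#' Intermediate shape trace of one branch
#'
#' Runs a single window through one branch in inference mode and reports
#' the dimensions of every stage's activation.
#'
#' @param object A `fallnet` or `fallnet_params` object.
#' @param batch Batch size of the probe input.
#' @return Named list of dimension vectors (`input`, `dsse1`, `pool`,
#'   `dsse2`, `tcn`, `feature`).
#' @export
shape_trace <- function(object, batch = 2) {
  net <- as_net(object)
  spec <- net$spec
  x <- array(stats::rnorm(spec$in_channels * spec$t_steps * batch),
             c(spec$in_channels, spec$t_steps, batch))
  tr <- cpp_branch_trace(net$params$branches[[1]], net$state$branches[[1]],
                         x, spec$gn_groups)
  list(input = dim(x), dsse1 = dim(tr$h1), pool = dim(tr$pooled),
       dsse2 = dim(tr$h2), tcn = dim(tr$tcn), feature = dim(tr$feat))
}

#' Empirical receptive field of the causal TCN
#'
#' Measures, by single-step input perturbation, how many trailing input
#' positions influence the final output step of the two-block causal
#' dilated TCN. For kernel 3 and dilations 1 and 2 the analytic value is
#' `1 + 2*(k-1)*(2^L - 1) = 13` steps.
#'
#' @param object A `fallnet` or `fallnet_params` object.
#' @param t_len Probe length (default 40 post-pool steps).
#' @param tol Change threshold distinguishing influence from none.
#' @return Integer: the number of input positions that influence the last
#'   output step.
#' @export
tcn_receptive_field <- function(object, t_len = 40, tol = 1e-12) {
  net <- as_net(object)
  spec <- net$spec
  ch <- spec$tcn_channels
  set.seed(7)
  x0 <- array(stats::rnorm(ch * t_len), c(ch, t_len, 1))
  bp <- net$params$branches[[1]]
  bs <- net$state$branches[[1]]
  base <- cpp_dstcn_forward(bp, bs, x0)[, t_len, 1]
  influenced <- logical(t_len)
  for (t in seq_len(t_len)) {
    xp <- x0
    xp[, t, 1] <- xp[, t, 1] + 1
    out <- cpp_dstcn_forward(bp, bs, xp)[, t_len, 1]
    influenced[t] <- max(abs(out - base)) > tol
  }
  sum(influenced)
}

#' Inference-mode class probabilities
#'
#' @param object A `fallnet` or `fallnet_params` object.
#' @param x Named list of stream arrays (3 x T x N), containing at least
#'   the streams named by the model's [fallnet_spec()], or a `window_set`.
#' @return Numeric vector of fall probabilities (one per window).
#' @export
fallnet_prob <- function(object, x) {
  net <- as_net(object)
  spec <- net$spec
  if (inherits(x, "window_set")) x <- x$x
  xs <- lapply(spec$streams, function(s) {
    if (is.null(x[[s]])) stop("missing input stream '", s, "'")
    x[[s]]
  })
  p <- cpp_fallnet_forward(net$params, net$state, xs, spec$gn_groups)
  as.numeric(p[2, ])
}
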