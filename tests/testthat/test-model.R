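test_that("separable convolutions reproduce the printed compression ratios and footprint", {
  set.seed(1)
  net <- fallnet_init(fallnet_spec())
  expect_equal(round(dsse_compression_ratio(net, 1), 2), 5.76)
  expect_equal(round(dsse_compression_ratio(net, 2), 2), 5.74)
  cp <- count_parameters(net)
  expect_lt(abs(cp$fp16_kb - 59.7) / 59.7, 0.02)
  # a 128 -> 48 linear layer alone holds 128*48 + 48 scalars
  expect_equal(length(net$params$head$fc1_W) + length(net$params$head$fc1_b),
               6192)
  # widening the branches strictly increases the parameter count
  wide <- fallnet_init(fallnet_spec(c1 = 32, c2 = 64, tcn_channels = 64,
                                    gn_groups = 8))
  expect_gt(count_parameters(wide)$n_params, cp$n_params)
})

test_that("branch shape trace follows the designed dimensions", {
  set.seed(2)
  net <- fallnet_init(fallnet_spec())
  tr <- shape_trace(net, batch = 3)
  expect_equal(tr$input[1:2], c(3, 87))
  expect_equal(tr$dsse1[1:2], c(16, 87))
  expect_equal(tr$pool[1:2], c(16, 43))
  expect_equal(tr$dsse2[1:2], c(32, 43))
  expect_equal(tr$tcn[1:2], c(32, 43))
  expect_equal(tr$feature, c(32, 3))
  expect_equal(ncol(net$params$head$fc1_W), 4 * 32)  # fused dimension
})

test_that("reduced variants consume the requested streams with matched head width", {
  set.seed(3)
  body <- fallnet_init(fallnet_spec(streams = c("ba", "bg")))
  expect_length(body$params$branches, 2)
  expect_equal(ncol(body$params$head$fc1_W), 64)
  expect_equal(body$spec$fused_dim, 64)
  full <- fallnet_init(fallnet_spec())
  expect_equal(full$spec$fused_dim, 128)
  expect_error(fallnet_spec(streams = character(0)))
})

test_that("TCN causality: perturbations propagate only forward in time", {
  set.seed(4)
  net <- fallnet_init(fallnet_spec())
  bp <- net$params$branches[[1]]
  bs <- net$state$branches[[1]]
  x <- array(rnorm(32 * 40), c(32, 40, 1))
  base <- dualfall:::cpp_dstcn_forward(bp, bs, x)
  expect_equal(dim(base), dim(x))  # length-preserving pad-and-crop
  for (tp in c(5, 17, 33)) {
    xp <- x
    xp[, tp, 1] <- xp[, tp, 1] + 1
    out <- dualfall:::cpp_dstcn_forward(bp, bs, xp)
    changed <- apply(abs(out[, , 1] - base[, , 1]), 2, max) > 1e-12
    expect_false(any(changed[seq_len(tp - 1)]))
    expect_true(changed[tp])
  }
})

test_that("empirical receptive field of the two dilated blocks is 13 steps", {
  set.seed(5)
  net <- fallnet_init(fallnet_spec())
  expect_equal(tcn_receptive_field(net), 13)
})

test_that("probability outputs are normalized, deterministic and per-sample pure", {
  set.seed(6)
  net <- fallnet_init(fallnet_spec())
  B <- 5
  xs <- list(ba = array(rnorm(3 * 87 * B), c(3, 87, B)),
             bg = array(rnorm(3 * 87 * B), c(3, 87, B)),
             ga = array(rnorm(3 * 87 * B), c(3, 87, B)),
             gg = array(rnorm(3 * 87 * B), c(3, 87, B)))
  p <- dualfall:::cpp_fallnet_forward(net$params, net$state,
                                      xs[net$spec$streams], net$spec$gn_groups)
  expect_equal(colSums(p), rep(1, B), tolerance = 1e-6)
  p2 <- dualfall:::cpp_fallnet_forward(net$params, net$state,
                                       xs[net$spec$streams], net$spec$gn_groups)
  expect_identical(p, p2)  # inference is bit-deterministic
  # permuting the batch permutes outputs identically
  perm <- c(3, 1, 5, 2, 4)
  xp <- lapply(xs, function(a) a[, , perm, drop = FALSE])
  pp <- dualfall:::cpp_fallnet_forward(net$params, net$state,
                                       xp[net$spec$streams], net$spec$gn_groups)
  expect_equal(pp, p[, perm], tolerance = 1e-12)
})

test_that("branches are parameter-isolated: editing one changes only its feature", {
  set.seed(7)
  net <- fallnet_init(fallnet_spec())
  x <- array(rnorm(3 * 87 * 2), c(3, 87, 2))
  feats <- function(n) lapply(1:4, function(i)
    dualfall:::cpp_branch_trace(n$params$branches[[i]], n$state$branches[[i]],
                                x, n$spec$gn_groups)$feat)
  f0 <- feats(net)
  net2 <- net
  net2$params$branches[[3]] <- lapply(net$params$branches[[3]],
                                      function(p) p * 0)
  f1 <- feats(net2)
  expect_identical(f0[[1]], f1[[1]])
  expect_identical(f0[[2]], f1[[2]])
  expect_identical(f0[[4]], f1[[4]])
  expect_false(identical(f0[[3]], f1[[3]]))
})

test_that("all-zero input yields zero features but in-range SE gates", {
  set.seed(8)
  net <- fallnet_init(fallnet_spec(se_bias = TRUE))
  x <- array(0, c(3, 87, 1))
  tr <- dualfall:::cpp_branch_trace(net$params$branches[[1]],
                                    net$state$branches[[1]], x,
                                    net$spec$gn_groups)
  expect_true(all(tr$h1 == 0))  # zero features rescaled by sigmoid stay zero
})

test_that("analytic gradients agree with finite differences", {
  spec <- fallnet_spec(t_steps = 24)
  set.seed(9)
  net <- fallnet_init(spec)
  B <- 3
  xs <- lapply(1:4, function(i) array(rnorm(3 * 24 * B), c(3, 24, B)))
  y <- c(0L, 1L, 1L)
  lg <- dualfall:::cpp_fallnet_loss_grad
  lossfun <- function(p) lg(p, net$state, xs, y, c(1, 1), 0.01, 0, 0,
                            spec$gn_groups, 0.1)$loss
  res <- lg(net$params, net$state, xs, y, c(1, 1), 0.01, 0, 0,
            spec$gn_groups, 0.1)
  eps <- 1e-6
  for (nm in c("d1_dw", "d2_pw", "d1_se_W2", "l1_pw2", "l2_dw1", "gn_g",
               "l2_bn2b")) {
    arr <- net$params$branches[[2]][[nm]]
    i <- ceiling(length(arr) / 2)
    p1 <- net$params; p1$branches[[2]][[nm]][i] <- arr[i] + eps
    p2 <- net$params; p2$branches[[2]][[nm]][i] <- arr[i] - eps
    fd <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
    an <- res$grads$branches[[2]][[nm]][i]
    expect_equal(an, fd, tolerance = 1e-4)
  }
  for (nm in c("fc1_W", "bn_g", "fc2_b")) {
    arr <- net$params$head[[nm]]
    i <- 1
    p1 <- net$params; p1$head[[nm]][i] <- arr[i] + eps
    p2 <- net$params; p2$head[[nm]][i] <- arr[i] - eps
    fd <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
    expect_equal(res$grads$head[[nm]][i], fd, tolerance = 1e-4)
  }
})
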