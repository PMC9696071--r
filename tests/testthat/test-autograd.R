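# The reverse-mode engine: every operation's gradient is checked against
# central finite differences on small random tensors.

rand_loss <- function(out) {
  rw <- array(stats::rnorm(length(out$value)),
              dim(out$value) %||% length(out$value))
  loss <- ag_tensor(sum(out$value * rw), list(out), function(g) list(g[1] * rw))
  list(loss = loss, rw = rw)
}

test_that("convolution gradients match finite differences", {
  set.seed(31)
  cases <- list(list(stride = c(1, 1), dil = c(1, 1), k = c(3, 3)),
                list(stride = c(2, 1), dil = c(1, 2), k = c(3, 3)),
                list(stride = c(1, 1), dil = c(2, 2), k = c(3, 3)),
                list(stride = c(1, 1), dil = c(1, 1), k = c(3, 1)),
                list(stride = c(1, 1), dil = c(1, 1), k = c(1, 3)))
  for (cs in cases) {
    x <- array(rnorm(6 * 5 * 2 * 2), c(6, 5, 2, 2))
    w <- array(rnorm(prod(cs$k) * 2 * 3), c(cs$k, 2, 3))
    b <- rnorm(3)
    fwd <- function(xv, wv, bv)
      ag_value(ns$ag_conv2d(ag_const(xv), ag_const(wv), ag_const(bv),
                            stride = cs$stride, dilation = cs$dil))
    xt <- ag_tensor(x, requires_grad = TRUE)
    wt <- ag_tensor(w, requires_grad = TRUE)
    bt <- ag_tensor(b, requires_grad = TRUE)
    out <- ns$ag_conv2d(xt, wt, bt, stride = cs$stride, dilation = cs$dil)
    rl <- rand_loss(out)
    ag_backward(rl$loss)
    expect_equal(xt$grad, fd_grad(function(v) sum(fwd(v, w, b) * rl$rw), x),
                 tolerance = 1e-6)
    expect_equal(wt$grad, fd_grad(function(v) sum(fwd(x, v, b) * rl$rw), w),
                 tolerance = 1e-6)
    expect_equal(as.numeric(bt$grad),
                 as.numeric(fd_grad(function(v) sum(fwd(x, w, v) * rl$rw), b)),
                 tolerance = 1e-6)
  }
})

test_that("convolution forward matches the plain-loop oracle", {
  set.seed(32)
  x <- array(rnorm(8 * 7 * 3), c(8, 7, 3))
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  got <- ag_value(ns$ag_conv2d(ag_const(array(x, c(8, 7, 3, 1))), ag_const(w),
                               stride = c(2, 1), dilation = c(1, 2)))
  expect_equal(got[, , , 1], oracle_conv2d(x, w, stride = c(2, 1),
                                           dilation = c(1, 2)),
               tolerance = 1e-12)
})

test_that("normalization, pooling and resampling gradients check out", {
  set.seed(33)
  # batch normalization (training statistics)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  gm <- ag_param(runif(3, 0.5, 1.5)); be <- ag_param(rnorm(3))
  st <- new.env(); st$running_mean <- rep(0, 3); st$running_var <- rep(1, 3)
  xt <- ag_tensor(x, requires_grad = TRUE)
  out <- ns$ag_batchnorm(xt, gm, be, st, training = TRUE)
  rl <- rand_loss(out); ag_backward(rl$loss)
  fwd_bn <- function(v) {
    s <- new.env(); s$running_mean <- rep(0, 3); s$running_var <- rep(1, 3)
    sum(ag_value(ns$ag_batchnorm(ag_const(v), ag_const(gm$value),
                                 ag_const(be$value), s, training = TRUE)) * rl$rw)
  }
  expect_equal(xt$grad, fd_grad(fwd_bn, x, eps = 1e-4), tolerance = 1e-4)
  expect_equal(as.numeric(gm$grad),
               as.numeric(fd_grad(function(v) {
                 s <- new.env(); s$running_mean <- rep(0, 3); s$running_var <- rep(1, 3)
                 sum(ag_value(ns$ag_batchnorm(ag_const(x), ag_const(v),
                                              ag_const(be$value), s,
                                              training = TRUE)) * rl$rw)
               }, gm$value, eps = 1e-4)), tolerance = 1e-4)

  # max pooling
  xt <- ag_tensor(array(rnorm(6 * 6 * 2 * 1), c(6, 6, 2, 1)), requires_grad = TRUE)
  out <- ns$ag_maxpool(xt, k = 3, stride = 2, pad = 1)
  expect_equal(dim(out$value), c(3, 3, 2, 1))
  rl <- rand_loss(out); ag_backward(rl$loss)
  expect_equal(xt$grad,
               fd_grad(function(v) sum(ag_value(ns$ag_maxpool(ag_const(v))) * rl$rw),
                       xt$value), tolerance = 1e-5)

  # bilinear interpolation (up and down)
  for (sz in list(c(9, 5), c(2, 3))) {
    xt <- ag_tensor(array(rnorm(4 * 4 * 2), c(4, 4, 2, 1)), requires_grad = TRUE)
    out <- ns$ag_interpolate(xt, sz[1], sz[2])
    rl <- rand_loss(out); ag_backward(rl$loss)
    expect_equal(xt$grad,
                 fd_grad(function(v)
                   sum(ag_value(ns$ag_interpolate(ag_const(v), sz[1], sz[2])) * rl$rw),
                   xt$value), tolerance = 1e-6)
  }
})

test_that("reduction and broadcast operations back-propagate correctly", {
  set.seed(34)
  x <- array(rnorm(5 * 4 * 3 * 2), c(5, 4, 3, 2))
  ops <- list(
    gap = function(t) ns$ag_global_avgpool(t),
    gmp = function(t) ns$ag_global_maxpool(t),
    cmean = function(t) ns$ag_channel_mean(t),
    cmax = function(t) ns$ag_channel_max(t))
  for (nm in names(ops)) {
    xt <- ag_tensor(x, requires_grad = TRUE)
    out <- ops[[nm]](xt)
    rl <- rand_loss(out); ag_backward(rl$loss)
    expect_equal(xt$grad,
                 fd_grad(function(v) sum(ag_value(ops[[nm]](ag_const(v))) * rl$rw), x),
                 tolerance = 1e-5, label = nm)
  }
  # channel and spatial gating, both arguments
  w <- matrix(runif(3 * 2), 3, 2)
  xt <- ag_tensor(x, requires_grad = TRUE); wt <- ag_tensor(w, requires_grad = TRUE)
  out <- ns$ag_scale_channels(xt, wt)
  rl <- rand_loss(out); ag_backward(rl$loss)
  expect_equal(xt$grad, fd_grad(function(v)
    sum(ag_value(ns$ag_scale_channels(ag_const(v), ag_const(w))) * rl$rw), x),
    tolerance = 1e-6)
  expect_equal(wt$grad, fd_grad(function(v)
    sum(ag_value(ns$ag_scale_channels(ag_const(x), ag_const(v))) * rl$rw), w),
    tolerance = 1e-6)
  m <- array(runif(5 * 4 * 1 * 2), c(5, 4, 1, 2))
  xt <- ag_tensor(x, requires_grad = TRUE); mt <- ag_tensor(m, requires_grad = TRUE)
  out <- ns$ag_scale_spatial(xt, mt)
  rl <- rand_loss(out); ag_backward(rl$loss)
  expect_equal(mt$grad, fd_grad(function(v)
    sum(ag_value(ns$ag_scale_spatial(ag_const(x), ag_const(v))) * rl$rw), m),
    tolerance = 1e-6)
})

test_that("softmax cross-entropy gradient and closed forms are correct", {
  set.seed(35)
  lab <- array(sample(0:4, 6 * 6 * 2, TRUE), c(6, 6, 2))
  lg <- ag_tensor(array(rnorm(6 * 6 * 5 * 2), c(6, 6, 5, 2)), requires_grad = TRUE)
  loss <- ns$ag_softmax_ce(lg, lab)
  ag_backward(loss)
  expect_equal(lg$grad,
               fd_grad(function(v) ag_value(ns$ag_softmax_ce(ag_const(v), lab)),
                       lg$value), tolerance = 1e-6)
  # uniform logits: loss = ln(K)
  expect_equal(ag_value(ns$ag_softmax_ce(ag_const(array(0, c(4, 4, 5, 1))),
                                         array(sample(0:4, 16, TRUE), c(4, 4, 1)))),
               log(5), tolerance = 1e-12)
  expect_error(ns$ag_softmax_ce(ag_const(array(0, c(2, 2, 3, 1))),
                                array(3L, c(2, 2, 1))), "invalid label")
})

test_that("gradients accumulate across shared parameters", {
  # a parameter used twice receives the sum of both path gradients
  p <- ag_param(matrix(2, 1, 1))
  a <- ns$ag_mul(p, p)            # p^2
  loss <- ag_tensor(a$value[1], list(a), function(g) list(array(g[1], c(1, 1))))
  ag_backward(loss)
  expect_equal(as.numeric(p$grad), 4)  # d(p^2)/dp = 2p
  ag_zero_grad(list(p))
  expect_null(p$grad)
})
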