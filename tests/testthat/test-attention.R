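# CBAM attention: channel gating, spatial gating, parameter accounting.

zero_attention_weights <- function(m) {
  m$w1$value[] <- 0
  m$w2$value[] <- 0
  for (cv in m$spatial) cv$w$value[] <- 0
  m
}

test_that("channel attention reduces to known closed forms", {
  set.seed(2)
  # zero MLP weights: Mc = sigmoid(0) = 0.5 everywhere
  m <- zero_attention_weights(nn_cbam(8, reduction_ratio = 4))
  f <- array(rnorm(5 * 5 * 8), c(5, 5, 8))
  expect_equal(as.numeric(ag_value(channel_attention(m, f))), rep(0.5, 8))
  # constant-per-channel input: avg pool equals max pool, Mc = sigmoid(2 MLP(v))
  m2 <- nn_cbam(4, reduction_ratio = 2)
  v <- c(1, -2, 0.5, 3)
  fc <- array(rep(v, each = 36), c(6, 6, 4))
  mlp <- function(x) as.numeric(m2$w2$value %*% pmax(m2$w1$value %*% x, 0))
  expect_equal(as.numeric(ag_value(channel_attention(m2, fc))),
               1 / (1 + exp(-2 * mlp(v))), tolerance = 1e-12)
})

test_that("channel attention matches an explicit-loop recomputation", {
  set.seed(12)
  for (rep in 1:3) {
    C <- sample(c(4, 8, 16), 1)
    m <- nn_cbam(C, reduction_ratio = 4)
    f <- array(rnorm(7 * 6 * C), c(7, 6, C))
    expect_equal(as.numeric(ag_value(channel_attention(m, f))),
                 oracle_channel_attention(f, m$w1$value, m$w2$value),
                 tolerance = 1e-12)
  }
})

test_that("spatial attention applies the variant's convolution to pooled maps", {
  set.seed(13)
  f <- array(rnorm(9 * 9 * 6), c(9, 9, 6))
  pooled <- array(0, c(9, 9, 2))
  pooled[, , 1] <- apply(f, c(1, 2), mean)
  pooled[, , 2] <- apply(f, c(1, 2), max)
  for (variant in c("conv7", "conv3_d2", "stacked2_conv3_d2")) {
    m <- nn_cbam(6, variant = variant)
    ms <- ag_value(spatial_attention(m, f))
    expect_equal(dim(ms), c(9, 9, 1, 1))
    expect_true(all(ms > 0 & ms < 1))
    # independent oracle: plain-loop convolution stack + sigmoid
    h <- pooled
    for (cv in m$spatial)
      h <- oracle_conv2d(h, cv$w$value, dilation = cv$dilation)
    expect_equal(as.numeric(ms), as.numeric(1 / (1 + exp(-h))),
                 tolerance = 1e-5)
  }
  # zero convolution weights: Ms = 0.5 everywhere
  mz <- zero_attention_weights(nn_cbam(6))
  expect_equal(as.numeric(ag_value(spatial_attention(mz, f))), rep(0.5, 81))
  expect_error(nn_cbam(6, variant = "conv5"))
})

test_that("cbam composes the two gates and preserves shape", {
  set.seed(14)
  for (shape in list(c(4, 4, 3), c(7, 5, 8), c(1, 9, 2))) {
    m <- nn_cbam(shape[3], reduction_ratio = 2)
    f <- array(rnorm(prod(shape)), shape)
    out <- ag_value(cbam(m, f))
    expect_equal(dim(out), c(shape, 1))
    # contraction: both gates are < 1 in magnitude
    expect_true(all(abs(out) <= abs(array(f, c(shape, 1)))))
    # equals sequential application of the sub-operations
    mc <- ag_value(channel_attention(m, f))
    fp <- array(f, c(shape, 1)) *
      array(rep(mc, each = shape[1] * shape[2]), c(shape, 1))
    ms <- ag_value(spatial_attention(m, fp))
    ms_b <- array(rep(as.numeric(ms), shape[3]),
                  c(shape[1], shape[2], shape[3], 1))
    expect_equal(out, fp * ms_b, tolerance = 1e-12)
    # gates forced to one: output equals input exactly
    ones_c <- ag_const(matrix(1, shape[3], 1))
    ones_s <- ag_const(array(1, c(shape[1], shape[2], 1, 1)))
    ft <- ag_const(array(f, c(shape, 1)))
    ident <- ns$ag_scale_spatial(ns$ag_scale_channels(ft, ones_c), ones_s)
    expect_identical(ag_value(ident), array(f, c(shape, 1)))
  }
})

test_that("attention outputs stay strictly inside (0, 1) on varied inputs", {
  set.seed(15)
  for (scale in c(1e-3, 1, 50)) {
    m <- nn_cbam(5, reduction_ratio = 2)
    f <- array(rnorm(6 * 6 * 5, sd = scale), c(6, 6, 5))
    mc <- ag_value(channel_attention(m, f))
    ms <- ag_value(spatial_attention(m, f))
    expect_true(all(mc > 0 & mc < 1))
    expect_true(all(ms > 0 & ms < 1))
  }
})

test_that("all attention parameters receive gradients", {
  set.seed(16)
  m <- nn_cbam(8, reduction_ratio = 4)
  f <- ag_const(array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2)))
  out <- cbam(m, f)
  rw <- array(rnorm(length(out$value)), dim(out$value))
  loss <- ag_tensor(sum(out$value * rw), list(out), function(g) list(g[1] * rw))
  ag_backward(loss)
  for (p in nn_parameters(m)) {
    expect_false(is.null(p$grad))
    expect_gt(max(abs(p$grad)), 0)
  }
})

test_that("spatial-attention parameter accounting is exact", {
  expect_identical(count_spatial_attention_params("conv3_d2", 1L), 18L)
  expect_identical(count_spatial_attention_params("conv7", 1L), 98L)
  expect_identical(count_spatial_attention_params("stacked2_conv3_d2", 1L), 54L)
  # added parameters of the stacked variant over the 3x3 baseline, 5 sites
  expect_identical(spatial_attention_param_delta("stacked2_conv3_d2", 5L), 180L)
  # counts agree with the instantiated modules' trainable spatial weights
  for (variant in c("conv7", "conv3_d2", "stacked2_conv3_d2")) {
    m <- nn_cbam(16, variant = variant)
    got <- sum(vapply(m$spatial, function(cv) length(cv$w$value), numeric(1)))
    expect_identical(as.integer(got), count_spatial_attention_params(variant, 1L))
  }
  # bias accounting follows the same scheme
  expect_identical(count_spatial_attention_params("stacked2_conv3_d2", 1L,
                                                  bias = TRUE), 57L)
})

test_that("receptive-field accounting follows the stacked-convolution formula", {
  expect_identical(receptive_field(list(c(7, 1))), 7L)
  expect_identical(receptive_field(list(c(3, 2))), 5L)
  expect_identical(receptive_field(list(c(3, 2), c(3, 2))), 9L)
  expect_identical(receptive_field(list()), 1L)
  expect_identical(receptive_field(list(c(3, 1), c(3, 1))), 5L)
  expect_error(receptive_field(list(c(4, 1))), "odd")
})

test_that("the ablation report tabulates all variants", {
  f <- tempfile(fileext = ".csv")
  df <- attention_ablation_report(n_modules = 5L, file = f)
  expect_equal(nrow(df), 3)
  expect_true(all(c("variant", "params_per_module", "added_params",
                    "receptive_field") %in% names(df)))
  expect_equal(df$added_params[df$variant == "conv3_d2"], 0L)
  expect_equal(df$added_params[df$variant == "stacked2_conv3_d2"], 180L)
  expect_true(file.exists(f))
  expect_equal(nrow(utils::read.csv(f)), 3)
})
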