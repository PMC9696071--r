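# Cascade network structure: shape contracts, asymmetric convolution,
# attention attachment accounting, feature fusion.

test_that("asymmetric convolution reproduces separable kernels and saves weights", {
  set.seed(41)
  # rank-1 kernel w = u v^T: the kx1 then 1xk stack is exactly equivalent
  for (rep in 1:5) {
    u <- rnorm(3); v <- rnorm(3)
    full_k <- array(outer(u, v), c(3, 3, 1, 1))
    asym <- nn_asymmetric_conv(1, 1, k = 3)
    asym$conv_kx1$w$value <- array(u, c(3, 1, 1, 1))
    asym$conv_1xk$w$value <- array(v, c(1, 3, 1, 1))
    x <- ag_const(array(rnorm(10 * 10), c(10, 10, 1, 1)))
    got <- ag_value(asym$forward(x))
    want <- ag_value(ns$ag_conv2d(x, ag_const(full_k)))
    expect_equal(got, want, tolerance = 1e-5)
  }
  # parameter count: 2k per channel pair instead of k^2
  a <- nn_asymmetric_conv(4, 4, k = 3)
  expect_equal(nn_count_parameters(a), 2 * 3 * 4 * 4)
  expect_lt(nn_count_parameters(a), nn_count_parameters(nn_conv(4, 4, k = 3)))
  # zero input stays zero (no bias)
  z <- ag_value(a$forward(ag_const(array(0, c(6, 6, 4, 1)))))
  expect_equal(z, array(0, c(6, 6, 4, 1)))
  expect_error(nn_asymmetric_conv(2, 2, k = 4), "odd")
})

test_that("branch outputs obey the cascade stride contract at several sizes", {
  for (base in c(64L, 96L, 128L)) {
    cfg <- network_config(base_size = base, width = 4L, fuse_channels = 8L,
                          seed = 2L)
    net <- cascade_network(cfg)
    img <- array(runif(base * base * 3, 0, 255), c(base, base, 3))
    out <- network_forward(net, img)
    expect_equal(dim(ag_value(out$f_low))[1:2], rep(base / 16L, 2))
    expect_equal(dim(ag_value(out$f_mid))[1:2], rep(base / 8L, 2))
    expect_equal(dim(ag_value(out$f_high))[1:2], rep(base / 8L, 2))
    expect_equal(dim(ag_value(out$final_logits)),
                 c(base / 4L, base / 4L, 5L, 1L))
    expect_equal(dim(ag_value(out$aux_logits_low))[3], 5L)
    expect_equal(dim(ag_value(out$aux_logits_mid))[3], 5L)
    mask <- predict_mask(net, img)
    expect_equal(dim(mask), c(base, base))
    expect_true(all(mask %in% 0:4))
  }
  expect_error(network_config(base_size = 100L), "divisible by 32")
  expect_error(network_config(num_classes = 1L), "num_classes")
  cfg <- network_config(base_size = 64L, width = 4L)
  net <- cascade_network(cfg)
  expect_error(network_forward(net, array(0, c(32, 32, 3))), "shape error")
})

test_that("inference is deterministic for fixed weights", {
  cfg <- tiny_config()
  net <- cascade_network(cfg)
  img <- generate_scene(scene_spec(seed = 3, size = 64))$image
  expect_identical(predict_mask(net, img), predict_mask(net, img))
  # identical config and seed rebuild to identical predictions
  net2 <- cascade_network(cfg)
  expect_identical(predict_mask(net, img), predict_mask(net2, img))
})

test_that("attention toggling changes structure exactly as designed", {
  cfg_on <- tiny_config()
  cfg_off <- tiny_config(use_cbam = FALSE)
  expect_length(ns$nn_find(cascade_network(cfg_on), "cbam"), 5)
  expect_length(ns$nn_find(cascade_network(cfg_off), "cbam"), 0)
  expect_length(ns$nn_find(cascade_network(tiny_config(baseline_icnet = TRUE)),
                           "cbam"), 0)
  # low branch: exactly 3 sites at its channel width
  d <- nn_count_parameters(build_low_branch(cfg_on)) -
    nn_count_parameters(build_low_branch(cfg_off))
  C <- 16L * cfg_on$width
  hidden <- max(1L, C %/% cfg_on$reduction_ratio)
  per_cbam <- 2L * C * hidden +
    count_spatial_attention_params(cfg_on$attention_variant, 1L)
  expect_identical(as.integer(d), 3L * per_cbam)
  # medium branch: exactly 2 sites
  dm <- nn_count_parameters(build_medium_branch(cfg_on)) -
    nn_count_parameters(build_medium_branch(tiny_config(use_cbam = FALSE,
                                                        use_asymmetric = TRUE)))
  Cm <- 8L * cfg_on$width
  hm <- max(1L, Cm %/% cfg_on$reduction_ratio)
  expect_identical(as.integer(dm),
                   2L * (2L * Cm * hm +
                           count_spatial_attention_params(cfg_on$attention_variant, 1L)))
})

test_that("asymmetric factorization swaps designated units without shape change", {
  cfg_asym <- tiny_config(use_cbam = FALSE)
  cfg_full <- tiny_config(use_cbam = FALSE, use_asymmetric = FALSE)
  med_a <- build_medium_branch(cfg_asym)
  med_f <- build_medium_branch(cfg_full)
  # exactly the last two trunk units carry the factorized convolution
  types <- function(branch) vapply(branch$units, function(u) u$conv2$type, "")
  expect_equal(types(med_a), c("conv", "conv", "conv", "asym_conv", "asym_conv"))
  expect_equal(types(med_f), rep("conv", 5))
  expect_lt(nn_count_parameters(med_a), nn_count_parameters(med_f))
  low_a <- build_low_branch(cfg_asym)
  expect_equal(vapply(low_a$units, function(u) u$conv2$type, ""),
               c("conv", "conv", "conv", rep("asym_conv", 3)))
  # output shapes identical either way
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  oa <- network_forward(cascade_network(cfg_asym), img)
  of <- network_forward(cascade_network(cfg_full), img)
  for (nm in names(oa))
    expect_identical(dim(ag_value(oa[[nm]])), dim(ag_value(of[[nm]])))
})

test_that("high branch has three stride-2 blocks", {
  cfg <- tiny_config()
  hb <- build_high_branch(cfg)
  expect_length(hb$blocks, 3)
  x <- ag_const(array(rnorm(64 * 64 * 3), c(64, 64, 3, 1)))
  expect_equal(dim(ag_value(hb$forward(x)))[1:2], c(8, 8))
  # zero weights propagate zero features
  for (p in nn_parameters(hb)) p$value[] <- 0
  expect_equal(max(abs(ag_value(hb$forward(x)))), 0)
})

test_that("cascade feature fusion upsamples, fuses and emits aux logits", {
  set.seed(43)
  cff <- nn_cff(6, 4, 8, num_classes = 5)
  f1 <- ag_const(array(rnorm(16 * 16 * 6), c(16, 16, 6, 1)))
  f2 <- ag_const(array(rnorm(32 * 32 * 4), c(32, 32, 4, 1)))
  out <- cff$forward(f1, f2, training = TRUE)
  expect_equal(dim(ag_value(out$fused)), c(32, 32, 8, 1))
  expect_equal(dim(ag_value(out$aux_logits)), c(32, 32, 5, 1))
  # wrong size ratio is a shape error
  f3 <- ag_const(array(rnorm(48 * 48 * 4), c(48, 48, 4, 1)))
  expect_error(cff$forward(f1, f3), "shape error")
  # zeroed F2 path: fused equals ReLU of the processed-F1 path
  cff$conv_proj$w$value[] <- 0
  cff$bn2$gamma$value[] <- 0
  cff$bn2$beta$value[] <- 0
  out2 <- cff$forward(f1, f2, training = TRUE)
  p1 <- cff$bn1$forward(cff$conv_dil$forward(
    ns$ag_interpolate(f1, 32, 32)), training = TRUE)
  expect_equal(ag_value(out2$fused), pmax(ag_value(p1), 0), tolerance = 1e-10)
})

test_that("checkpoints restore the exact network state", {
  cfg <- tiny_config()
  net <- cascade_network(cfg)
  scenes <- tiny_scenes(2)
  sgd_fit(net, scenes$images, scenes$masks, steps = 3,
          tc = train_config(batch_size = 2, seed = 5))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  img <- scenes$images[[1]]
  expect_identical(predict_mask(net, img), predict_mask(net2, img))
  expect_error(suppressWarnings(load_checkpoint(tempfile())))
})
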