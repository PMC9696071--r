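# Improved three-branch cascade segmentation network.
#
# The medium-resolution branch is a residual trunk (7x7 stem convolution with
# max pooling, then five bottleneck units) applied to the half-scale input;
# its output sits at stride 8 relative to the full-resolution image. The
# low-resolution branch continues from those features (shared stem, as in the
# original cascade design) through a 2x downsample and six further bottleneck
# units with dilation 2, giving stride 16. The high-resolution branch is a
# lightweight three-block stack on the full image, stride 8. Cascade feature
# fusion (CFF) merges low into medium, then the result into high, each fusion
# emitting auxiliary logits for deep supervision; a final 1x1 classifier at
# quarter resolution produces the segmentation logits.
#
# Attention (CBAM) is attached outside the last three bottleneck units of the
# low branch and the last two of the medium branch (five sites); asymmetric
# 3x1/1x3 factorization replaces the 3x3 convolutions of those same units.

#' Network configuration
#'
#' @param num_classes number of mask classes including background (default 5).
#' @param base_size input side length; must be divisible by 32 (default 512).
#' @param use_cbam attach CBAM attention modules (5 sites)?
#' @param attention_variant spatial-attention convolution variant, see
#'   [nn_cbam()].
#' @param use_asymmetric replace designated 3x3 convolutions by 3x1 + 1x3
#'   factorized stacks?
#' @param baseline_icnet `TRUE` disables both modifications, yielding the
#'   unmodified cascade network.
#' @param width stem channel count; bottleneck widths scale with it. The
#'   50-layer residual reference design corresponds to `width = 64`; smaller
#'   values give proportionally lighter networks.
#' @param fuse_channels channel count of the fused CFF representations.
#' @param reduction_ratio channel-attention MLP bottleneck ratio.
#' @param share_stem share the stem/trunk computation between the medium and
#'   low branches (the original cascade design); `FALSE` gives the low branch
#'   its own trunk on the quarter-scale input.
#' @param dropout 2-D dropout rate before the final classifier.
#' @param seed RNG seed for weight initialization.
#' @return a `network_config` list.
#' @export
network_config <- function(num_classes = 5L, base_size = 512L, use_cbam = TRUE,
                           attention_variant = "stacked2_conv3_d2",
                           use_asymmetric = TRUE, baseline_icnet = FALSE,
                           width = 64L, fuse_channels = 128L,
                           reduction_ratio = 16L, share_stem = TRUE,
                           dropout = 0.1, seed = 1L) {
  if (base_size %% 32L != 0L)
    stop("config error: base_size must be divisible by 32")
  if (num_classes < 2L) stop("config error: num_classes must be >= 2")
  attention_variant <- match.arg(attention_variant, SPATIAL_VARIANTS)
  if (baseline_icnet) {
    use_cbam <- FALSE
    use_asymmetric <- FALSE
  }
  structure(list(num_classes = as.integer(num_classes),
                 base_size = as.integer(base_size),
                 use_cbam = isTRUE(use_cbam),
                 attention_variant = attention_variant,
                 use_asymmetric = isTRUE(use_asymmetric),
                 baseline_icnet = isTRUE(baseline_icnet),
                 width = as.integer(width),
                 fuse_channels = as.integer(fuse_channels),
                 reduction_ratio = as.integer(reduction_ratio),
                 share_stem = isTRUE(share_stem),
                 dropout = dropout,
                 seed = as.integer(seed)),
            class = "network_config")
}

# Residual bottleneck unit (1x1 -> 3x3 -> 1x1 with identity/projection skip),
# optionally with an asymmetric middle convolution and CBAM gating attached
# after the residual addition.
nn_bottleneck <- function(in_c, mid_c, out_c, stride = 1L, dilation = 1L,
                          asymmetric = FALSE, cbam = NULL) {
  conv1 <- nn_conv(in_c, mid_c, k = 1L)
  bn1 <- nn_batchnorm(mid_c)
  conv2 <- if (asymmetric)
    nn_asymmetric_conv(mid_c, mid_c, k = 3L, stride = stride, dilation = dilation)
  else
    nn_conv(mid_c, mid_c, k = 3L, stride = stride, dilation = dilation)
  bn2 <- nn_batchnorm(mid_c)
  conv3 <- nn_conv(mid_c, out_c, k = 1L)
  bn3 <- nn_batchnorm(out_c)
  proj <- if (in_c != out_c || stride != 1L)
    list(conv = nn_conv(in_c, out_c, k = 1L, stride = stride),
         bn = nn_batchnorm(out_c))
  else NULL
  new_module("bottleneck",
             list(conv1 = conv1, bn1 = bn1, conv2 = conv2, bn2 = bn2,
                  conv3 = conv3, bn3 = bn3, proj = proj, cbam = cbam,
                  in_c = in_c, out_c = out_c),
             function(x, training = FALSE) {
               h <- ag_relu(bn1$forward(conv1$forward(x, training), training))
               h <- ag_relu(bn2$forward(conv2$forward(h, training), training))
               h <- bn3$forward(conv3$forward(h, training), training)
               skip <- if (is.null(proj)) x
                       else proj$bn$forward(proj$conv$forward(x, training), training)
               y <- ag_relu(ag_add(h, skip))
               if (!is.null(cbam)) y <- cbam$forward(y, training)
               y
             })
}

make_cbam_if <- function(enable, channels, config) {
  if (!enable) return(NULL)
  nn_cbam(channels, variant = config$attention_variant,
          reduction_ratio = config$reduction_ratio)
}

# Stem + five bottleneck units; `with_mods` enables the CBAM/asymmetric
# modifications on the last two units (the medium branch's modification
# sites).
build_trunk <- function(config, with_mods = TRUE) {
  w <- config$width
  stem_conv <- nn_conv(3L, w, k = 7L, stride = 2L)
  stem_bn <- nn_batchnorm(w)
  units <- list(
    nn_bottleneck(w, w, 4L * w),
    nn_bottleneck(4L * w, w, 4L * w),
    nn_bottleneck(4L * w, w, 4L * w),
    nn_bottleneck(4L * w, 2L * w, 8L * w,
                  asymmetric = with_mods && config$use_asymmetric,
                  cbam = make_cbam_if(with_mods && config$use_cbam, 8L * w, config)),
    nn_bottleneck(8L * w, 2L * w, 8L * w,
                  asymmetric = with_mods && config$use_asymmetric,
                  cbam = make_cbam_if(with_mods && config$use_cbam, 8L * w, config))
  )
  new_module("trunk",
             list(stem_conv = stem_conv, stem_bn = stem_bn, units = units,
                  out_c = 8L * config$width),
             function(x, training = FALSE) {
               h <- ag_relu(stem_bn$forward(stem_conv$forward(x, training), training))
               h <- ag_maxpool(h, k = 3L, stride = 2L, pad = 1L)
               for (u in units) h <- u$forward(h, training)
               h
             })
}

#' Build the medium-resolution branch
#'
#' Stem (7x7 convolution, stride 2, max pooling) plus the first five
#' bottleneck units; operates on the half-scale input and outputs features at
#' stride 8 relative to the full image. When enabled, the last two units
#' carry CBAM attention and asymmetric middle convolutions.
#'
#' @param config a [network_config()].
#' @return an `nn_module` with `out_c` channels `8 * width`.
#' @export
build_medium_branch <- function(config) {
  with_seed_local(config$seed + 1L, build_trunk(config, with_mods = TRUE))
}

#' Build the low-resolution branch
#'
#' Six bottleneck units with dilation 2 (stride 1) continuing the trunk at
#' stride 16; the last three units carry the CBAM/asymmetric modifications.
#' With `share_stem = TRUE` (default) the branch consumes the medium branch's
#' features after a 2x downsample; otherwise it owns an unmodified trunk copy
#' applied to the quarter-scale input.
#'
#' @param config a [network_config()].
#' @return an `nn_module` with `out_c` channels `16 * width`.
#' @export
build_low_branch <- function(config) {
  w <- config$width
  with_seed_local(config$seed + 2L, {
    trunk <- if (config$share_stem) NULL else build_trunk(config, with_mods = FALSE)
    mods <- function(i) i >= 4L  # last three of the six units
    units <- lapply(1:6, function(i)
      nn_bottleneck(if (i == 1L) 8L * w else 16L * w, 4L * w, 16L * w,
                    dilation = 2L,
                    asymmetric = mods(i) && config$use_asymmetric,
                    cbam = make_cbam_if(mods(i) && config$use_cbam, 16L * w, config)))
    new_module("low_branch",
               list(trunk = trunk, units = units, out_c = 16L * w),
               function(x, training = FALSE) {
                 if (!is.null(trunk)) {
                   h <- trunk$forward(x, training)
                 } else {
                   dm <- dim(ag_value(x))
                   h <- ag_interpolate(x, dm[1] %/% 2L, dm[2] %/% 2L)
                 }
                 for (u in units) h <- u$forward(h, training)
                 h
               })
  })
}

#' Build the high-resolution branch
#'
#' Three lightweight blocks on the full-resolution input, each: 3x3
#' convolution (stride 2), ReLU, batch normalization, 1x1 convolution, ReLU.
#' Output stride 8.
#'
#' @param config a [network_config()].
#' @return an `nn_module` with `out_c` channels equal to `width`.
#' @export
build_high_branch <- function(config) {
  w <- config$width
  widths <- c(max(1L, w %/% 2L), max(1L, w %/% 2L), w)
  with_seed_local(config$seed + 3L, {
    blocks <- list()
    in_c <- 3L
    for (i in 1:3) {
      conv3 <- nn_conv(in_c, widths[i], k = 3L, stride = 2L)
      bn <- nn_batchnorm(widths[i])
      conv1 <- nn_conv(widths[i], widths[i], k = 1L)
      blocks[[i]] <- new_module("high_block",
                                list(conv3 = conv3, bn = bn, conv1 = conv1),
                                local({
                                  c3 <- conv3; b <- bn; c1 <- conv1
                                  function(x, training = FALSE) {
                                    h <- ag_relu(c3$forward(x, training))
                                    h <- b$forward(h, training)
                                    ag_relu(c1$forward(h, training))
                                  }
                                }))
      in_c <- widths[i]
    }
    new_module("high_branch", list(blocks = blocks, out_c = w),
               function(x, training = FALSE) {
                 for (b in blocks) x <- b$forward(x, training)
                 x
               })
  })
}

#' Cascade feature fusion module
#'
#' Fuses a coarser map `F1` with a finer map `F2`: `F1` is bilinearly
#' upsampled to `F2`'s size, refined by a 3x3 dilation-2 convolution with
#' batch normalization, and summed with the 1x1-projected, normalized `F2`;
#' ReLU gives the fused output. An auxiliary 1x1 classifier on the processed
#' `F1` path provides label guidance for deep supervision.
#'
#' `F2` must be the same size as `F1` or exactly twice its size (the upsample
#' step is skipped when the sizes already match).
#'
#' @param c1,c2 channel counts of `F1` and `F2`.
#' @param fuse_c fused channel count.
#' @param num_classes channels of the auxiliary logits.
#' @return an `nn_module` whose `forward(f1, f2, training)` returns
#'   `list(fused, aux_logits)`.
#' @export
nn_cff <- function(c1, c2, fuse_c, num_classes) {
  conv_dil <- nn_conv(c1, fuse_c, k = 3L, dilation = 2L)
  bn1 <- nn_batchnorm(fuse_c)
  conv_proj <- nn_conv(c2, fuse_c, k = 1L)
  bn2 <- nn_batchnorm(fuse_c)
  aux_head <- nn_conv(fuse_c, num_classes, k = 1L, bias = TRUE)
  m <- new_module("cff",
                  list(conv_dil = conv_dil, bn1 = bn1, conv_proj = conv_proj,
                       bn2 = bn2, aux_head = aux_head, out_c = fuse_c),
                  NULL)
  m$forward <- function(f1, f2, training = FALSE) {
    d1 <- dim(ag_value(f1)); d2 <- dim(ag_value(f2))
    if (all(d2[1:2] == 2L * d1[1:2])) {
      f1 <- ag_interpolate(f1, d2[1], d2[2])
    } else if (!all(d2[1:2] == d1[1:2])) {
      stop("shape error: F2 must match F1 or be exactly twice its size")
    }
    p1 <- bn1$forward(conv_dil$forward(f1, training), training)
    aux <- aux_head$forward(p1, training)
    p2 <- bn2$forward(conv_proj$forward(f2, training), training)
    list(fused = ag_relu(ag_add(p1, p2)), aux_logits = aux)
  }
  m
}

#' Build the full cascade segmentation network
#'
#' @param config a [network_config()].
#' @return an `nn_module` of type `cascade_net`. Use [network_forward()] to
#'   run it and [predict_mask()] for inference.
#' @export
cascade_network <- function(config = network_config()) {
  medium <- build_medium_branch(config)
  low <- build_low_branch(config)
  high <- build_high_branch(config)
  with_seed_local(config$seed + 4L, {
    cff1 <- nn_cff(low$out_c, medium$out_c, config$fuse_channels,
                   config$num_classes)
    cff2 <- nn_cff(config$fuse_channels, high$out_c, config$fuse_channels,
                   config$num_classes)
    classifier <- nn_conv(config$fuse_channels, config$num_classes, k = 1L,
                          bias = TRUE)
    new_module("cascade_net",
               list(config = config, medium = medium, low = low, high = high,
                    cff1 = cff1, cff2 = cff2, classifier = classifier),
               NULL)
  })
}

normalize_input <- function(x) (x / 255 - 0.5) / 0.25

#' Run the cascade network
#'
#' @param net a [cascade_network()].
#' @param images `(H, W, 3)` array, `(H, W, 3, N)` array or list of images
#'   with values in 0..255; side length must equal `config$base_size`.
#' @param training `TRUE` enables batch-statistic normalization and dropout.
#' @return list of `ag_tensor`s: `f_low`, `f_mid`, `f_high` (branch
#'   features), `aux_logits_low`, `aux_logits_mid` (CFF label guidance) and
#'   `final_logits` (quarter-resolution class scores).
#' @export
network_forward <- function(net, images, training = FALSE) {
  config <- net$config
  x <- stack_images(images)
  dm <- dim(x)
  if (dm[1] != config$base_size || dm[2] != config$base_size || dm[3] != 3L)
    stop("shape error: expected ", config$base_size, "x", config$base_size,
         "x3 input, got ", paste(dm, collapse = "x"))
  x <- ag_const(normalize_input(x))
  half <- config$base_size %/% 2L
  x_half <- ag_interpolate(x, half, half)
  f_mid <- net$medium$forward(x_half, training)
  f_low <- if (config$share_stem) {
    net$low$forward(f_mid, training)
  } else {
    quarter <- config$base_size %/% 4L
    net$low$forward(ag_interpolate(x, quarter, quarter), training)
  }
  f_high <- net$high$forward(x, training)
  fus1 <- net$cff1$forward(f_low, f_mid, training)
  fus2 <- net$cff2$forward(fus1$fused, f_high, training)
  dmf <- dim(ag_value(fus2$fused))
  up <- ag_interpolate(fus2$fused, 2L * dmf[1], 2L * dmf[2])
  up <- ag_dropout(up, config$dropout, training)
  final_logits <- net$classifier$forward(up, training)
  list(f_low = f_low, f_mid = f_mid, f_high = f_high,
       aux_logits_low = fus1$aux_logits, aux_logits_mid = fus2$aux_logits,
       final_logits = final_logits)
}

#' Predict segmentation masks
#'
#' Runs the network in inference mode, bilinearly upsamples the final logits
#' to full resolution and takes the per-pixel argmax.
#'
#' @param net a [cascade_network()].
#' @param images input image(s), see [network_forward()].
#' @return integer mask `(H, W)` for a single image, `(H, W, N)` for a batch,
#'   with class ids `0 .. num_classes - 1`.
#' @export
predict_mask <- function(net, images) {
  single <- !is.list(images) && length(dim(images)) == 3L
  out <- network_forward(net, images, training = FALSE)
  logits <- ag_value(out$final_logits)
  size <- net$config$base_size
  dm <- dim(logits)
  full <- array(bilinear_fwd_cpp(as.numeric(logits), dm[1], dm[2], dm[3], dm[4],
                                 size, size), c(size, size, dm[3], dm[4]))
  K <- dm[3]; N <- dm[4]
  mask <- array(0L, c(size, size, N))
  for (n in seq_len(N)) {
    M <- matrix(full[, , , n], ncol = K)
    mask[, , n] <- array(max.col(M, ties.method = "first") - 1L, c(size, size))
  }
  if (single) mask[, , 1] else mask
}

#' Save / load network checkpoints
#'
#' Checkpoints store the configuration, all parameter values and batch-norm
#' running statistics, with a structure version tag.
#'
#' @param net a [cascade_network()].
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(format = "dentalseg-checkpoint", version = 1L,
               config = net$config, state = nn_state(net)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the reconstructed network.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "dentalseg-checkpoint"))
    stop("not a dentalseg checkpoint: ", path)
  net <- cascade_network(ck$config)
  nn_load_state(net, ck$state)
  net
}
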