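# Convolutional block attention (CBAM): channel attention gates each feature
# channel using a shared two-layer MLP applied to global average- and
# max-pooled descriptors; spatial attention gates each location using a
# convolution over the channel-wise mean and max maps. The spatial
# convolution comes in three variants: the original single 7x7 kernel, a
# single 3x3 kernel with dilation 2, and the stacked pair of 3x3 dilation-2
# kernels (2->2 then 2->1) that this package's improved network uses.

SPATIAL_VARIANTS <- c("conv7", "conv3_d2", "stacked2_conv3_d2")

spatial_conv_stack <- function(variant, bias = FALSE) {
  switch(variant,
    conv7 = list(nn_conv(2L, 1L, k = 7L, bias = bias)),
    conv3_d2 = list(nn_conv(2L, 1L, k = 3L, dilation = 2L, bias = bias)),
    stacked2_conv3_d2 = list(
      nn_conv(2L, 2L, k = 3L, dilation = 2L, bias = bias),
      nn_conv(2L, 1L, k = 3L, dilation = 2L, bias = bias)),
    stop("invalid config: unknown spatial attention variant '", variant, "'")
  )
}

#' CBAM attention module
#'
#' Builds a convolutional block attention module for feature maps with
#' `channels` channels: sequential channel attention then spatial attention,
#' both sigmoid-gated.
#'
#' @param channels number of input channels.
#' @param variant spatial-attention convolution: `"conv7"` (original 7x7),
#'   `"conv3_d2"` (single 3x3, dilation 2) or `"stacked2_conv3_d2"` (two
#'   stacked 3x3 dilation-2 convolutions, the improved design).
#' @param reduction_ratio bottleneck ratio of the shared channel MLP
#'   (hidden width `max(1, channels %/% reduction_ratio)`).
#' @param bias include bias terms in the attention convolutions (default
#'   `FALSE`).
#' @return an `nn_module`; its `forward` applies full CBAM gating.
#' @export
nn_cbam <- function(channels, variant = "stacked2_conv3_d2",
                    reduction_ratio = 16L, bias = FALSE) {
  variant <- match.arg(variant, SPATIAL_VARIANTS)
  if (reduction_ratio < 1) stop("invalid config: reduction_ratio must be >= 1")
  hidden <- max(1L, channels %/% as.integer(reduction_ratio))
  w1 <- ag_param(matrix(stats::rnorm(hidden * channels, 0, sqrt(2 / channels)),
                        hidden, channels))
  w2 <- ag_param(matrix(stats::rnorm(channels * hidden, 0, sqrt(2 / hidden)),
                        channels, hidden))
  stack <- spatial_conv_stack(variant, bias)
  m <- new_module("cbam",
                  list(w1 = w1, w2 = w2, spatial = stack, channels = channels,
                       variant = variant, reduction_ratio = reduction_ratio),
                  NULL)
  m$forward <- function(x, training = FALSE) cbam_gate(m, x, training)
  m
}

as_feature_tensor <- function(f) {
  if (is_ag(f)) return(f)
  if (is.matrix(f)) f <- array(f, c(dim(f), 1L))
  if (length(dim(f)) == 2L) f <- array(f, c(dim(f), 1L, 1L))
  if (length(dim(f)) == 3L) f <- array(f, c(dim(f), 1L))
  if (length(dim(f)) != 4L) stop("feature map must have 3 or 4 dimensions")
  ag_const(f)
}

mlp_forward <- function(module, v) {
  h <- ag_relu(ag_linear(v, module$w1))
  ag_linear(h, module$w2)
}

#' Channel attention weights
#'
#' `Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))` with a shared two-layer
#' MLP (`C -> C/r -> C`, ReLU in between) applied to the global average- and
#' max-pooled channel descriptors.
#'
#' @param module an [nn_cbam()] module.
#' @param f feature map, `(H, W, C)` array, `(H, W, C, N)` array or
#'   `ag_tensor`.
#' @return `ag_tensor` of shape `(C, N)` with entries strictly in (0, 1).
#' @export
channel_attention <- function(module, f) {
  f <- as_feature_tensor(f)
  if (any(dim(f$value)[1:3] < 1L)) stop("empty feature map")
  if (dim(f$value)[3] != module$channels)
    stop("feature map has ", dim(f$value)[3], " channels, module expects ",
         module$channels)
  avg <- mlp_forward(module, ag_global_avgpool(f))
  mx <- mlp_forward(module, ag_global_maxpool(f))
  ag_sigmoid(ag_add(avg, mx))
}

#' Spatial attention map
#'
#' Concatenates the channel-wise mean and max maps (2 x H x W) and applies
#' the variant's convolution stack followed by a sigmoid; "same" padding
#' preserves the spatial size.
#'
#' @inheritParams channel_attention
#' @return `ag_tensor` of shape `(H, W, 1, N)` with entries strictly in (0, 1).
#' @export
spatial_attention <- function(module, f) {
  f <- as_feature_tensor(f)
  if (dim(f$value)[3] < 1L) stop("empty feature map")
  pooled <- ag_concat_channels(ag_channel_mean(f), ag_channel_max(f))
  for (cv in module$spatial) pooled <- cv$forward(pooled)
  ag_sigmoid(pooled)
}

# Full CBAM gating: F' = Mc (.) F over channels, F'' = Ms (.) F' over space.
cbam_gate <- function(module, f, training = FALSE) {
  f <- as_feature_tensor(f)
  mc <- channel_attention(module, f)
  fprime <- ag_scale_channels(f, mc)
  ms <- spatial_attention(module, fprime)
  ag_scale_spatial(fprime, ms)
}

#' Apply CBAM attention to a feature map
#'
#' @inheritParams channel_attention
#' @param training forwarded to sub-layers (CBAM itself has no train-time
#'   stochasticity).
#' @return gated feature map with the same shape as the input.
#' @export
cbam <- function(module, f, training = FALSE) cbam_gate(module, f, training)

#' Exact parameter count of a spatial-attention convolution stack
#'
#' Counts the trainable weights of the chosen spatial-attention variant
#' (2-channel pooled input; `stacked2_conv3_d2` uses a 2->2 then 2->1 stack),
#' multiplied by the number of attention modules in the network.
#'
#' @param variant one of `"conv7"`, `"conv3_d2"`, `"stacked2_conv3_d2"`.
#' @param n_modules number of CBAM attachment sites (>= 1).
#' @param bias count bias terms as well (default `FALSE`).
#' @return integer weight count.
#' @export
count_spatial_attention_params <- function(variant, n_modules = 1L,
                                           bias = FALSE) {
  variant <- match.arg(variant, SPATIAL_VARIANTS)
  if (n_modules < 1) stop("n_modules must be >= 1")
  per <- switch(variant,
    conv7 = 7L * 7L * 2L * 1L + if (bias) 1L else 0L,
    conv3_d2 = 3L * 3L * 2L * 1L + if (bias) 1L else 0L,
    stacked2_conv3_d2 = (3L * 3L * 2L * 2L + if (bias) 2L else 0L) +
      (3L * 3L * 2L * 1L + if (bias) 1L else 0L))
  as.integer(per) * as.integer(n_modules)
}

#' Added-parameter delta of a spatial-attention variant
#'
#' Parameter increment of `variant` over the single dilated 3x3 baseline,
#' summed over all attention sites — the accounting behind the ablation
#' comparison of the three variants.
#'
#' @inheritParams count_spatial_attention_params
#' @param baseline variant used as the zero point (default `"conv3_d2"`).
#' @export
spatial_attention_param_delta <- function(variant, n_modules = 5L,
                                          baseline = "conv3_d2", bias = FALSE) {
  count_spatial_attention_params(variant, n_modules, bias) -
    count_spatial_attention_params(baseline, n_modules, bias)
}

#' Receptive field of a stack of (possibly dilated) convolutions
#'
#' Standard formula `RF = 1 + sum_i d_i * (k_i - 1)` for stride-1 stacks.
#' Note that a single 3x3 convolution with dilation 2 has RF 5 (not 7), and
#' two stacked ones have RF 9; the formula value is reported as-is.
#'
#' @param kernel_dilation_list list of `c(k, d)` pairs (or a 2-column
#'   matrix); all `k` odd, `d >= 1`. An empty list yields 1.
#' @return integer receptive-field side length.
#' @export
receptive_field <- function(kernel_dilation_list) {
  if (is.matrix(kernel_dilation_list))
    kernel_dilation_list <- asplit(kernel_dilation_list, 1)
  if (length(kernel_dilation_list) == 0L) return(1L)
  rf <- 1L
  for (kd in kernel_dilation_list) {
    k <- as.integer(kd[[1]]); d <- as.integer(kd[[2]])
    if (k %% 2L == 0L) stop("kernel sizes must be odd")
    if (d < 1L) stop("dilation must be >= 1")
    rf <- rf + d * (k - 1L)
  }
  rf
}

variant_kernel_spec <- function(variant) {
  switch(variant,
    conv7 = list(c(7L, 1L)),
    conv3_d2 = list(c(3L, 2L)),
    stacked2_conv3_d2 = list(c(3L, 2L), c(3L, 2L)))
}

#' Spatial-attention ablation report
#'
#' Tabulates, for each spatial-attention variant, the per-module parameter
#' count, the added parameters over the dilated 3x3 baseline across all
#' attention sites, and the receptive field.
#'
#' @param n_modules number of CBAM attachment sites (default 5: three on the
#'   low-resolution branch, two on the medium-resolution branch).
#' @param bias count convolution biases?
#' @param file optional path; when given the table is also written as CSV.
#' @return a `data.frame`.
#' @export
attention_ablation_report <- function(n_modules = 5L, bias = FALSE,
                                      file = NULL) {
  df <- data.frame(
    variant = SPATIAL_VARIANTS,
    params_per_module = vapply(SPATIAL_VARIANTS, count_spatial_attention_params,
                               integer(1), n_modules = 1L, bias = bias),
    added_params = vapply(SPATIAL_VARIANTS, spatial_attention_param_delta,
                          integer(1), n_modules = n_modules, bias = bias),
    receptive_field = vapply(SPATIAL_VARIANTS, function(v)
      as.integer(receptive_field(variant_kernel_spec(v))), integer(1)),
    row.names = NULL
  )
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
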