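# Layer constructors. A module is a list with class "nn_module": a `type`
# tag, parameter tensors / child modules as fields, and a `forward(x,
# training)` closure. Parameters are discovered by recursive traversal
# (`nn_parameters`), so anything stored in the list is trainable state.

new_module <- function(type, fields, forward) {
  m <- c(list(type = type), fields)
  m$forward <- forward
  class(m) <- "nn_module"
  m
}

#' @export
print.nn_module <- function(x, ...) {
  cat("<nn_module:", x$type, "|", format(nn_count_parameters(x), big.mark = ","),
      "parameters>\n")
  invisible(x)
}

#' Collect trainable parameters of a module tree
#' @param module an `nn_module`.
#' @return flat list of parameter `ag_tensor`s.
#' @export
nn_parameters <- function(module) {
  out <- list()
  walk <- function(x) {
    if (is_ag(x)) {
      if (x$requires) out[[length(out) + 1L]] <<- x
    } else if (inherits(x, "nn_module") || (is.list(x) && !is.function(x))) {
      for (el in x) if (!is.function(el)) walk(el)
    }
  }
  walk(module)
  out
}

#' Count trainable parameters of a module tree
#' @param module an `nn_module`.
#' @return integer number of scalar weights.
#' @export
nn_count_parameters <- function(module) {
  sum(vapply(nn_parameters(module), function(p) length(p$value), numeric(1)))
}

# Find all submodules of a given type (structural introspection).
nn_find <- function(module, type) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "nn_module")) {
      if (x$type == type) out[[length(out) + 1L]] <<- x
      for (el in x) if (!is.function(el)) walk(el)
    } else if (is.list(x) && !is.function(x)) {
      for (el in x) if (!is.function(el)) walk(el)
    }
  }
  walk(module)
  out
}

he_init <- function(kh, kw, in_c, out_c) {
  array(stats::rnorm(kh * kw * in_c * out_c, 0, sqrt(2 / (kh * kw * in_c))),
        c(kh, kw, in_c, out_c))
}

#' 2-D convolution layer
#'
#' @param in_c,out_c input / output channel counts.
#' @param k kernel size, length-2 (rows, cols) or scalar.
#' @param stride,dilation integer, scalar or length-2.
#' @param pad `NULL` for "same" padding (odd kernels), or explicit length-2.
#' @param bias include an additive bias term?
#' @return an `nn_module`.
#' @export
nn_conv <- function(in_c, out_c, k = 3L, stride = 1L, dilation = 1L,
                    pad = NULL, bias = FALSE) {
  k <- rep(as.integer(k), length.out = 2)
  w <- ag_param(he_init(k[1], k[2], in_c, out_c))
  b <- if (bias) ag_param(numeric(out_c)) else NULL
  new_module("conv",
             list(w = w, b = b, k = k, stride = stride, dilation = dilation,
                  pad = pad, in_c = in_c, out_c = out_c),
             function(x, training = FALSE)
               ag_conv2d(x, w, b, stride = stride, pad = pad, dilation = dilation))
}

#' Asymmetric (factorized) convolution layer
#'
#' Replaces a k x k convolution by a k x 1 convolution followed by a 1 x k
#' convolution with no nonlinearity in between. Per input/output channel pair
#' this uses 2k weights instead of k^2; it reproduces any rank-1 (separable)
#' k x k kernel exactly.
#'
#' @inheritParams nn_conv
#' @param k odd kernel size >= 3.
#' @export
nn_asymmetric_conv <- function(in_c, out_c, k = 3L, stride = 1L, dilation = 1L,
                               bias = FALSE) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 3L) stop("invalid config: k must be odd and >= 3")
  cv <- nn_conv(in_c, out_c, k = c(k, 1L), stride = c(stride, 1L),
                dilation = c(dilation, 1L), bias = FALSE)
  ch <- nn_conv(out_c, out_c, k = c(1L, k), stride = c(1L, stride),
                dilation = c(1L, dilation), bias = bias)
  new_module("asym_conv", list(conv_kx1 = cv, conv_1xk = ch, k = k,
                               in_c = in_c, out_c = out_c),
             function(x, training = FALSE)
               ch$forward(cv$forward(x, training), training))
}

#' Batch normalization layer
#' @param c number of channels.
#' @param momentum running-statistics update rate.
#' @param eps variance floor.
#' @export
nn_batchnorm <- function(c, momentum = 0.1, eps = 1e-5) {
  gamma <- ag_param(rep(1, c))
  beta <- ag_param(rep(0, c))
  gamma$no_decay <- TRUE  # norm affine terms are exempt from weight decay
  beta$no_decay <- TRUE
  state <- new.env(parent = emptyenv())
  state$running_mean <- rep(0, c)
  state$running_var <- rep(1, c)
  new_module("batchnorm", list(gamma = gamma, beta = beta, state = state,
                               c = c),
             function(x, training = FALSE)
               ag_batchnorm(x, gamma, beta, state, training = training,
                            momentum = momentum, eps = eps))
}

#' Sequential container
#' @param ... `nn_module`s applied in order.
#' @export
nn_sequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && !inherits(mods[[1]], "nn_module"))
    mods <- mods[[1]]
  new_module("sequential", list(layers = mods), function(x, training = FALSE) {
    for (m in mods) x <- m$forward(x, training)
    x
  })
}

nn_relu <- function() new_module("relu", list(),
                                 function(x, training = FALSE) ag_relu(x))

# Serialize / restore parameter values and batch-norm running statistics.
nn_state <- function(module) {
  params <- lapply(nn_parameters(module), function(p) p$value)
  bn <- lapply(nn_find(module, "batchnorm"), function(b)
    list(mean = b$state$running_mean, var = b$state$running_var))
  list(params = params, bn = bn)
}

nn_load_state <- function(module, state) {
  params <- nn_parameters(module)
  if (length(params) != length(state$params))
    stop("checkpoint does not match network structure")
  for (i in seq_along(params)) {
    if (!identical(dim(params[[i]]$value), dim(state$params[[i]])) &&
        length(params[[i]]$value) != length(state$params[[i]]))
      stop("checkpoint parameter ", i, " has wrong shape")
    params[[i]]$value <- state$params[[i]]
  }
  bns <- nn_find(module, "batchnorm")
  for (i in seq_along(bns)) {
    bns[[i]]$state$running_mean <- state$bn[[i]]$mean
    bns[[i]]$state$running_var <- state$bn[[i]]$var
  }
  invisible(module)
}
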