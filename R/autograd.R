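#' @useDynLib dentalseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Reverse-mode automatic differentiation on a define-by-run tape.
#
# A tensor is an environment holding a numeric array (`value`), its gradient
# accumulator (`grad`), the tensors it was computed from (`parents`) and a
# closure (`backward_fn`) mapping the output gradient to a list of parent
# gradients. `ag_backward()` topologically sorts the graph reachable from a
# scalar loss and accumulates gradients into every tensor created with
# `requires_grad = TRUE`. Shapes follow the (H, W, C, N) layout used by the
# C++ kernels.

.ag <- new.env(parent = emptyenv())
.ag$id <- 0L

#' Create an autodiff tensor
#'
#' Wraps a numeric array as a node of the automatic-differentiation graph.
#' Most users never call this directly; layer constructors and network
#' builders do.
#'
#' @param value numeric array (any shape; scalars allowed).
#' @param parents list of parent `ag_tensor`s this value was computed from.
#' @param backward function mapping the gradient at this node to a list of
#'   gradients for `parents` (use `NULL` entries to skip a parent).
#' @param requires_grad should gradients be accumulated here (leaf parameter)?
#' @return an object of class `ag_tensor`.
#' @export
ag_tensor <- function(value, parents = list(), backward = NULL,
                      requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  .ag$id <- .ag$id + 1L
  t$id <- .ag$id
  t$value <- value
  t$grad <- NULL
  t$parents <- parents
  t$backward_fn <- backward
  t$requires <- requires_grad ||
    any(vapply(parents, function(p) p$requires, logical(1)))
  t$leaf <- requires_grad
  class(t) <- "ag_tensor"
  t
}

#' @rdname ag_tensor
#' @export
ag_param <- function(value) ag_tensor(value, requires_grad = TRUE)

#' @rdname ag_tensor
#' @export
ag_const <- function(value) ag_tensor(value)

is_ag <- function(x) inherits(x, "ag_tensor")

#' Extract the value of a tensor
#' @param x an `ag_tensor` (plain arrays pass through).
#' @return the underlying numeric array.
#' @export
ag_value <- function(x) if (is_ag(x)) x$value else x

#' @export
print.ag_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag_tensor", if (is.null(d)) length(x$value) else paste(d, collapse = "x"),
      if (x$requires) "grad" else "", ">\n")
  invisible(x)
}

# Topological order of the graph reachable from `root` (iterative DFS; the
# tape can be deeper than R's recursion limit for large networks).
ag_topo <- function(root) {
  seen <- new.env(parent = emptyenv())
  topo <- vector("list", 256L)
  nt <- 0L
  stack <- list(list(node = root, stage = 1L))
  ns <- 1L
  while (ns > 0L) {
    fr <- stack[[ns]]
    ns <- ns - 1L
    node <- fr$node
    key <- as.character(node$id)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      ns <- ns + 1L
      stack[[ns]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (p$requires && is.null(seen[[as.character(p$id)]])) {
          ns <- ns + 1L
          stack[[ns]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- node
    }
  }
  topo[seq_len(nt)]
}

#' Backpropagate gradients from a scalar loss
#'
#' Accumulates gradients into every reachable leaf tensor created with
#' `requires_grad = TRUE`. Intermediate gradients are released as soon as
#' they have been consumed.
#'
#' @param root scalar `ag_tensor` (typically a loss).
#' @param grad optional seed gradient (defaults to 1).
#' @export
ag_backward <- function(root, grad = NULL) {
  if (!root$requires) return(invisible(NULL))
  if (is.null(grad)) grad <- array(1, dim = if (is.null(dim(root$value))) length(root$value) else dim(root$value))
  root$grad <- grad
  topo <- ag_topo(root)
  for (i in rev(seq_along(topo))) {
    node <- topo[[i]]
    g <- node$grad
    if (is.null(g) || is.null(node$backward_fn)) next
    pgrads <- node$backward_fn(g)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      pg <- pgrads[[j]]
      if (!p$requires || is.null(pg)) next
      p$grad <- if (is.null(p$grad)) pg else p$grad + pg
    }
    if (!node$leaf) node$grad <- NULL  # free non-parameter gradients
  }
  invisible(NULL)
}

#' Reset accumulated gradients on a list of parameters
#' @param params list of `ag_tensor`s.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise ops --------------------------------------------------------

ag_relu <- function(x) {
  v <- ag_value(x)
  ag_tensor(pmax(v, 0), list(x), function(g) list(g * (v > 0)))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-ag_value(x)))
  ag_tensor(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_add <- function(a, b) {
  ag_tensor(ag_value(a) + ag_value(b), list(a, b), function(g) list(g, g))
}

ag_mul <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_tensor(va * vb, list(a, b), function(g) list(g * vb, g * va))
}

ag_scale <- function(x, s) {  # scalar constant s
  ag_tensor(ag_value(x) * s, list(x), function(g) list(g * s))
}

# ---- convolution ------------------------------------------------------------

conv_out_size <- function(n, k, s, p, d) (n + 2 * p - d * (k - 1) - 1) %/% s + 1

# "same" padding for odd kernels
same_pad <- function(k, d) d * (k - 1) %/% 2

# x: (H, W, C, N); w: (kh, kw, inC, outC); b: length outC or NULL.
ag_conv2d <- function(x, w, b = NULL, stride = c(1L, 1L), pad = NULL,
                      dilation = c(1L, 1L)) {
  v <- ag_value(x)
  wv <- ag_value(w)
  dm <- dim(v); H <- dm[1]; W <- dm[2]; C <- dm[3]; N <- dm[4]
  kd <- dim(wv); kh <- kd[1]; kw <- kd[2]
  stopifnot(kd[3] == C)
  outC <- kd[4]
  stride <- rep(as.integer(stride), length.out = 2)
  dilation <- rep(as.integer(dilation), length.out = 2)
  if (is.null(pad)) pad <- c(same_pad(kh, dilation[1]), same_pad(kw, dilation[2]))
  pad <- rep(as.integer(pad), length.out = 2)
  OH <- conv_out_size(H, kh, stride[1], pad[1], dilation[1])
  OW <- conv_out_size(W, kw, stride[2], pad[2], dilation[2])
  cols <- im2col_cpp(as.numeric(v), H, W, C, N, kh, kw, stride[1], stride[2],
                     pad[1], pad[2], dilation[1], dilation[2])
  wm <- matrix(wv, nrow = kh * kw * C, ncol = outC)
  out <- crossprod(wm, cols)                       # outC x (OH*OW*N)
  y <- aperm(array(out, c(outC, OH, OW, N)), c(2, 3, 1, 4))
  parents <- list(x, w)
  if (!is.null(b)) {
    bv <- ag_value(b)
    y <- y + array(rep(bv, each = OH * OW), c(OH, OW, outC, N))
    parents <- c(parents, list(b))
  }
  ag_tensor(y, parents, function(g) {
    gmat <- matrix(aperm(g, c(3, 1, 2, 4)), nrow = outC)
    dw <- NULL; dx <- NULL; db <- NULL
    if (w$requires) dw <- array(tcrossprod(cols, gmat), dim = kd)
    if (x$requires) {
      dcols <- wm %*% gmat
      dx <- array(col2im_cpp(dcols, H, W, C, N, kh, kw, stride[1], stride[2],
                             pad[1], pad[2], dilation[1], dilation[2]), dim = dm)
    }
    if (!is.null(b) && b$requires)
      db <- as.numeric(apply(g, 3, sum))
    if (is.null(b)) list(dx, dw) else list(dx, dw, db)
  })
}

# ---- batch normalization ----------------------------------------------------

to_cmat <- function(v) {
  dm <- dim(v)
  matrix(aperm(v, c(1, 2, 4, 3)), ncol = dm[3])
}
from_cmat <- function(m, dm) {
  aperm(array(m, c(dm[1], dm[2], dm[4], dm[3])), c(1, 2, 4, 3))
}

# gamma, beta: length-C params; state: environment with running_mean/var.
ag_batchnorm <- function(x, gamma, beta, state, training = FALSE,
                         momentum = 0.1, eps = 1e-5) {
  v <- ag_value(x)
  dm <- dim(v)
  M <- to_cmat(v)
  m <- nrow(M)
  gv <- ag_value(gamma); bv <- ag_value(beta)
  if (!is.null(state$momentum)) momentum <- state$momentum
  if (training) {
    mu <- colMeans(M)
    xc <- sweep(M, 2, mu)
    va <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
    xc <- sweep(M, 2, mu)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, istd, "*")
  y <- from_cmat(sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+"), dm)
  ag_tensor(y, list(x, gamma, beta), function(g) {
    G <- to_cmat(g)
    dgamma <- if (gamma$requires) colSums(G * xhat) else NULL
    dbeta <- if (beta$requires) colSums(G) else NULL
    dx <- NULL
    if (x$requires) {
      dxhat <- sweep(G, 2, gv, "*")
      if (training) {
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * xhat)
        dM <- sweep(dxhat - matrix(s1 / m, m, ncol(G), byrow = TRUE) -
                      sweep(xhat, 2, s2 / m, "*"), 2, istd, "*")
      } else {
        dM <- sweep(dxhat, 2, istd, "*")
      }
      dx <- from_cmat(dM, dm)
    }
    list(dx, dgamma, dbeta)
  })
}

# ---- pooling and spatial reductions ----------------------------------------

ag_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  v <- ag_value(x)
  dm <- dim(v)
  OH <- (dm[1] + 2 * pad - k) %/% stride + 1
  OW <- (dm[2] + 2 * pad - k) %/% stride + 1
  res <- maxpool_fwd_cpp(as.numeric(v), dm[1], dm[2], dm[3], dm[4], k, stride, pad)
  y <- array(res$value, c(OH, OW, dm[3], dm[4]))
  arg <- res$argmax
  ag_tensor(y, list(x), function(g)
    list(array(maxpool_bwd_cpp(as.numeric(g), arg, prod(dm)), dim = dm)))
}

# Global average pool: (H,W,C,N) -> (C,N)
ag_global_avgpool <- function(x) {
  v <- ag_value(x)
  dm <- dim(v)
  y <- matrix(colMeans(matrix(v, nrow = dm[1] * dm[2])), dm[3], dm[4])
  ag_tensor(y, list(x), function(g)
    list(array(rep(as.numeric(g), each = dm[1] * dm[2]) / (dm[1] * dm[2]), dim = dm)))
}

# Global max pool: (H,W,C,N) -> (C,N)
ag_global_maxpool <- function(x) {
  v <- ag_value(x)
  dm <- dim(v)
  M <- matrix(v, nrow = dm[1] * dm[2])
  arg <- max.col(t(M), ties.method = "first")
  y <- matrix(M[cbind(arg, seq_len(ncol(M)))], dm[3], dm[4])
  ag_tensor(y, list(x), function(g) {
    dM <- matrix(0, nrow(M), ncol(M))
    dM[cbind(arg, seq_len(ncol(M)))] <- as.numeric(g)
    list(array(dM, dim = dm))
  })
}

# Channel-wise mean / max maps: (H,W,C,N) -> (H,W,1,N)
ag_channel_mean <- function(x) {
  v <- ag_value(x)
  dm <- dim(v)
  hw <- dm[1] * dm[2]
  A <- array(aperm(v, c(1, 2, 4, 3)), c(hw * dm[4], dm[3]))
  y <- array(rowMeans(A), c(dm[1], dm[2], 1, dm[4]))
  ag_tensor(y, list(x), function(g) {
    gv <- as.numeric(g) / dm[3]
    list(aperm(array(rep(gv, dm[3]), c(dm[1], dm[2], dm[4], dm[3])), c(1, 2, 4, 3)))
  })
}

ag_channel_max <- function(x) {
  v <- ag_value(x)
  dm <- dim(v)
  hw <- dm[1] * dm[2]
  A <- matrix(aperm(v, c(1, 2, 4, 3)), nrow = hw * dm[4], ncol = dm[3])
  arg <- max.col(A, ties.method = "first")
  rows <- seq_len(nrow(A))
  y <- array(A[cbind(rows, arg)], c(dm[1], dm[2], 1, dm[4]))
  ag_tensor(y, list(x), function(g) {
    dA <- matrix(0, nrow(A), ncol(A))
    dA[cbind(rows, arg)] <- as.numeric(g)
    list(aperm(array(dA, c(dm[1], dm[2], dm[4], dm[3])), c(1, 2, 4, 3)))
  })
}

ag_concat_channels <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  da <- dim(va); db_ <- dim(vb)
  stopifnot(all(da[c(1, 2, 4)] == db_[c(1, 2, 4)]))
  y <- array(0, c(da[1], da[2], da[3] + db_[3], da[4]))
  y[, , seq_len(da[3]), ] <- va
  y[, , da[3] + seq_len(db_[3]), ] <- vb
  ag_tensor(y, list(a, b), function(g)
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db_[3]), , drop = FALSE]))
}

# ---- broadcast multiplications (attention gating) ---------------------------

# x: (H,W,C,N), w: (C,N) -> y[h,w,c,n] = x * w[c,n]
ag_scale_channels <- function(x, w) {
  v <- ag_value(x); wv <- ag_value(w)
  dm <- dim(v)
  wexp <- array(rep(as.numeric(wv), each = dm[1] * dm[2]), dim = dm)
  ag_tensor(v * wexp, list(x, w), function(g) {
    dx <- if (x$requires) g * wexp else NULL
    dw <- if (w$requires)
      matrix(colSums(matrix(g * v, nrow = dm[1] * dm[2])), dm[3], dm[4]) else NULL
    list(dx, dw)
  })
}

# x: (H,W,C,N), m: (H,W,1,N) -> y[h,w,c,n] = x * m[h,w,1,n]
ag_scale_spatial <- function(x, m) {
  v <- ag_value(x); mv <- ag_value(m)
  dm <- dim(v)
  mexp <- aperm(array(rep(as.numeric(mv), dm[3]), c(dm[1], dm[2], dm[4], dm[3])),
                c(1, 2, 4, 3))
  ag_tensor(v * mexp, list(x, m), function(g) {
    dx <- if (x$requires) g * mexp else NULL
    dmv <- NULL
    if (m$requires) {
      s <- g * v
      dmv <- array(0, dim(mv))
      for (c in seq_len(dm[3])) dmv <- dmv + s[, , c, , drop = FALSE]
    }
    list(dx, dmv)
  })
}

# ---- linear (used by the channel-attention MLP) -----------------------------

# x: (inC, N) matrix; w: (outC, inC); b: length outC or NULL
ag_linear <- function(x, w, b = NULL) {
  v <- ag_value(x); wv <- ag_value(w)
  y <- wv %*% v
  parents <- list(x, w)
  if (!is.null(b)) {
    y <- y + ag_value(b)
    parents <- c(parents, list(b))
  }
  ag_tensor(y, parents, function(g) {
    dx <- if (x$requires) crossprod(wv, g) else NULL
    dw <- if (w$requires) tcrossprod(g, v) else NULL
    if (is.null(b)) list(dx, dw) else list(dx, dw, rowSums(g))
  })
}

# ---- resampling -------------------------------------------------------------

ag_interpolate <- function(x, out_h, out_w) {
  v <- ag_value(x)
  dm <- dim(v)
  y <- array(bilinear_fwd_cpp(as.numeric(v), dm[1], dm[2], dm[3], dm[4],
                              out_h, out_w), c(out_h, out_w, dm[3], dm[4]))
  ag_tensor(y, list(x), function(g)
    list(array(bilinear_bwd_cpp(as.numeric(g), out_h, out_w, dm[3], dm[4],
                                dm[1], dm[2]), dim = dm)))
}

# ---- dropout ----------------------------------------------------------------

ag_dropout <- function(x, p, training = FALSE) {
  if (!training || p <= 0) return(x)
  v <- ag_value(x)
  mask <- array((stats::runif(length(v)) >= p) / (1 - p), dim(v))
  ag_tensor(v * mask, list(x), function(g) list(g * mask))
}

# ---- softmax cross-entropy --------------------------------------------------

# logits: (h, w, K, N); labels: (h, w, N) integer array with values 0..K-1.
ag_softmax_ce <- function(logits, labels) {
  v <- ag_value(logits)
  dm <- dim(v)
  K <- dm[3]
  lab <- as.integer(labels)
  if (any(lab < 0L) || any(lab >= K))
    stop("invalid label: class ids must lie in 0..", K - 1)
  M <- matrix(aperm(v, c(1, 2, 4, 3)), ncol = K)
  if (length(lab) != nrow(M)) stop("label shape does not match logits")
  mx <- do.call(pmax, lapply(seq_len(K), function(k) M[, k]))
  E <- exp(M - mx)
  Z <- rowSums(E)
  picked <- M[cbind(seq_len(nrow(M)), lab + 1L)]
  loss <- mean(-(picked - mx - log(Z)))
  ag_tensor(loss, list(logits), function(g) {
    P <- E / Z
    P[cbind(seq_len(nrow(P)), lab + 1L)] <- P[cbind(seq_len(nrow(P)), lab + 1L)] - 1
    dM <- P * (as.numeric(g) / nrow(P))
    list(aperm(array(dM, c(dm[1], dm[2], dm[4], dm[3])), c(1, 2, 4, 3)))
  })
}
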