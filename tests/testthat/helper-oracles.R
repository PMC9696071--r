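# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, set arithmetic) so they share no code
# path with the implementations they check.

# Plain-loop 2-D convolution of a (H, W, C) array with kernel (kh, kw, C,
# outC), zero padding, arbitrary stride/dilation.
oracle_conv2d <- function(x, w, stride = c(1, 1), pad = NULL, dilation = c(1, 1)) {
  dm <- dim(x); kd <- dim(w)
  stride <- rep(stride, length.out = 2); dilation <- rep(dilation, length.out = 2)
  if (is.null(pad)) pad <- c(dilation[1] * (kd[1] - 1) %/% 2,
                             dilation[2] * (kd[2] - 1) %/% 2)
  OH <- (dm[1] + 2 * pad[1] - dilation[1] * (kd[1] - 1) - 1) %/% stride[1] + 1
  OW <- (dm[2] + 2 * pad[2] - dilation[2] * (kd[2] - 1) - 1) %/% stride[2] + 1
  out <- array(0, c(OH, OW, kd[4]))
  for (oc in seq_len(kd[4]))
    for (oh in seq_len(OH))
      for (ow in seq_len(OW)) {
        acc <- 0
        for (c in seq_len(dm[3]))
          for (i in seq_len(kd[1]))
            for (j in seq_len(kd[2])) {
              h0 <- (oh - 1) * stride[1] - pad[1] + (i - 1) * dilation[1] + 1
              w0 <- (ow - 1) * stride[2] - pad[2] + (j - 1) * dilation[2] + 1
              if (h0 >= 1 && h0 <= dm[1] && w0 >= 1 && w0 <= dm[2])
                acc <- acc + x[h0, w0, c] * w[i, j, c, oc]
            }
        out[oh, ow, oc] <- acc
      }
  out
}

# All-pairs ACE chromatic adjustment with the same summation order as the
# production kernel (columns outer, rows inner) so agreement is exact.
oracle_ace_rc <- function(channel, T) {
  H <- nrow(channel); W <- ncol(channel)
  rc <- matrix(0, H, W)
  for (pw in seq_len(W))
    for (ph in seq_len(H)) {
      acc <- 0
      for (jw in seq_len(W))
        for (jh in seq_len(H)) {
          if (jh == ph && jw == pw) next
          r <- min(max((channel[ph, pw] - channel[jh, jw]) / T, -1), 1)
          acc <- acc + r / sqrt((ph - jh)^2 + (pw - jw)^2)
        }
      rc[ph, pw] <- acc
    }
  rc
}

# Per-class set-arithmetic IoU / accuracy / macro-F1 from raw masks.
oracle_mask_metrics <- function(pred, label, k) {
  ious <- c(); f1s <- c()
  for (cls in 0:(k - 1)) {
    inter <- sum(pred == cls & label == cls)
    uni <- sum(pred == cls | label == cls)
    if (uni > 0) ious <- c(ious, inter / uni)
    np <- sum(pred == cls); nl <- sum(label == cls)
    if (np + nl > 0) {
      prec <- if (np > 0) inter / np else 0
      rec <- if (nl > 0) inter / nl else 0
      f1s <- c(f1s, if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
    }
  }
  list(miou = mean(ious), acc = mean(pred == label), f1 = mean(f1s))
}

# Explicit-loop channel attention (shared MLP on pooled descriptors).
oracle_channel_attention <- function(f, w1, w2) {
  C <- dim(f)[3]
  avg <- vapply(seq_len(C), function(c) mean(f[, , c]), numeric(1))
  mx <- vapply(seq_len(C), function(c) max(f[, , c]), numeric(1))
  mlp <- function(v) as.numeric(w2 %*% pmax(w1 %*% v, 0))
  1 / (1 + exp(-(mlp(avg) + mlp(mx))))
}

fd_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_config <- function(...) {
  args <- list(base_size = 64L, width = 4L, fuse_channels = 8L, seed = 1L)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(network_config, args)
}

tiny_scenes <- function(n, size = 64L, seed0 = 100L) {
  scenes <- lapply(seq_len(n), function(i)
    generate_scene(scene_spec(seed = seed0 + i, size = size)))
  list(images = lapply(scenes, `[[`, "image"),
       masks = lapply(scenes, `[[`, "mask"))
}

ns <- asNamespace("dentalseg")
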