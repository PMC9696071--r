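# Evaluation metrics over the (k+1) x (k+1) confusion matrix P, with
# P[i, j] = number of pixels of true class i predicted as class j, and the
# weighted multi-branch cross-entropy training loss.

#' Confusion matrix of a predicted mask
#'
#' @param pred,label integer masks of identical shape with class ids in
#'   `0 .. k`.
#' @param n_classes total class count `k + 1`.
#' @return `n_classes x n_classes` integer matrix; rows index the true class,
#'   columns the predicted class, both labelled `0 .. k`.
#' @export
confusion_matrix <- function(pred, label, n_classes = 5L) {
  if (!identical(dim(pred), dim(label)) && length(pred) != length(label))
    stop("pred and label must have the same shape")
  p <- as.integer(pred); l <- as.integer(label)
  k <- as.integer(n_classes)
  if (any(p < 0L | p >= k) || any(l < 0L | l >= k))
    stop("class ids must lie in 0..", k - 1L)
  counts <- tabulate(l * k + p + 1L, nbins = k * k)
  P <- matrix(counts, k, k, byrow = TRUE)
  dimnames(P) <- list(true = 0:(k - 1L), pred = 0:(k - 1L))
  P
}

check_cm <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P) || any(P < 0))
    stop("P must be a square non-negative count matrix")
  if (sum(P) == 0) stop("undefined metric: confusion matrix is all zero")
}

per_class_iou <- function(P) {
  tp <- diag(P)
  union <- rowSums(P) + colSums(P) - tp
  ifelse(union > 0, tp / union, NA_real_)
}

#' Mean intersection-over-union
#'
#' Mean over classes of `P_ii / (sum_j P_ij + sum_j P_ji - P_ii)`. Classes
#' absent from both prediction and reference (empty union) are excluded from
#' the mean.
#'
#' @param P confusion matrix from [confusion_matrix()].
#' @return value in `[0, 1]`.
#' @export
miou <- function(P) {
  check_cm(P)
  mean(per_class_iou(P), na.rm = TRUE)
}

#' Overall pixel accuracy
#' @param P confusion matrix.
#' @return `trace(P) / sum(P)`, in `[0, 1]`.
#' @export
pixel_acc <- function(P) {
  check_cm(P)
  sum(diag(P)) / sum(P)
}

#' Mean per-class (balanced) pixel accuracy
#' @param P confusion matrix.
#' @return mean over classes with any reference pixels of the per-class
#'   recall.
#' @export
mean_class_acc <- function(P) {
  check_cm(P)
  rs <- rowSums(P)
  mean(ifelse(rs > 0, diag(P) / rs, NA_real_), na.rm = TRUE)
}

#' Macro-averaged F1 score
#'
#' Per class, `F1 = 2 * precision * recall / (precision + recall)`; classes
#' absent from both prediction and reference are excluded from the macro
#' mean. A class with zero precision+recall scores 0.
#'
#' @param P confusion matrix.
#' @return value in `[0, 1]`.
#' @export
f1 <- function(P) {
  check_cm(P)
  tp <- diag(P)
  rs <- rowSums(P)  # reference pixels per class
  cs <- colSums(P)  # predicted pixels per class
  f <- numeric(nrow(P))
  present <- (rs + cs) > 0
  prec <- ifelse(cs > 0, tp / cs, 0)
  rec <- ifelse(rs > 0, tp / rs, 0)
  denom <- prec + rec
  f <- ifelse(denom > 0, 2 * prec * rec / denom, 0)
  mean(f[present])
}

#' Metrics report from a confusion matrix
#'
#' @param P confusion matrix.
#' @param class_names optional class labels.
#' @return list with `per_class` data.frame (IoU, precision, recall, pixel
#'   counts) and scalar `acc`, `mean_class_acc`, `miou`, `f1`.
#' @export
metrics_report <- function(P, class_names = NULL) {
  check_cm(P)
  k <- nrow(P)
  if (is.null(class_names)) class_names <- paste0("class", 0:(k - 1L))
  tp <- diag(P); rs <- rowSums(P); cs <- colSums(P)
  per_class <- data.frame(
    class = class_names,
    iou = per_class_iou(P),
    precision = ifelse(cs > 0, tp / cs, NA_real_),
    recall = ifelse(rs > 0, tp / rs, NA_real_),
    ref_pixels = rs,
    pred_pixels = cs,
    row.names = NULL)
  list(per_class = per_class, acc = pixel_acc(P),
       mean_class_acc = mean_class_acc(P), miou = miou(P), f1 = f1(P))
}

#' Write a metrics report to JSON and/or CSV
#' @param report from [metrics_report()].
#' @param json,csv optional output paths.
#' @export
write_metrics_report <- function(report, json = NULL, csv = NULL) {
  if (!is.null(json))
    jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(csv))
    utils::write.csv(report$per_class, csv, row.names = FALSE)
  invisible(report)
}

#' Cascade loss weights
#'
#' Branch weights of the weighted multi-branch cross-entropy: the
#' high-resolution (final) branch carries weight `w1 = 1`, the medium and low
#' auxiliary branches `w2 = 0.4` and `w3 = 0.16`.
#'
#' @param w1,w2,w3 non-negative branch weights.
#' @return named numeric vector.
#' @export
cascade_weights <- function(w1 = 1, w2 = 0.4, w3 = 0.16) {
  w <- c(w1 = w1, w2 = w2, w3 = w3)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be non-negative")
  w
}

# Nearest-neighbor downsample of a label stack (H, W, N) to (h, w, N).
downsample_labels <- function(labels, h, w) {
  resize_mask_nearest(labels, h, w)
}

#' Weighted cascade cross-entropy loss
#'
#' `L = w1 * L1 + w2 * L2 + w3 * L3` where `L1` is the softmax cross-entropy
#' of the final (high-resolution-path) logits, and `L2`, `L3` those of the
#' medium and low auxiliary logits, each against the label nearest-neighbor
#' downsampled to the logit map's size.
#'
#' @param logits list with elements `final_logits`, `aux_logits_mid`,
#'   `aux_logits_low` (`ag_tensor`s or plain `(h, w, K, N)` arrays), e.g. the
#'   output of [network_forward()].
#' @param label integer label array `(H, W)` or `(H, W, N)` with values
#'   `0 .. K-1` at full resolution.
#' @param weights from [cascade_weights()].
#' @return scalar `ag_tensor` (use `ag_value()` for the number).
#' @export
cascade_loss <- function(logits, label, weights = cascade_weights()) {
  label <- stack_masks(label)
  triple <- list(logits$final_logits, logits$aux_logits_mid, logits$aux_logits_low)
  if (any(vapply(triple, is.null, logical(1))))
    stop("logits must contain final_logits, aux_logits_mid and aux_logits_low")
  total <- NULL
  for (i in 1:3) {
    lg <- triple[[i]]
    if (!is_ag(lg)) lg <- ag_const(lg)
    dm <- dim(lg$value)
    li <- ag_softmax_ce(lg, downsample_labels(label, dm[1], dm[2]))
    term <- ag_scale(li, weights[[i]])
    total <- if (is.null(total)) term else ag_add(total, term)
  }
  total
}
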