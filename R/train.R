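# Training, evaluation and prediction pipeline.

#' Training configuration
#'
#' @param lr initial SGD learning rate (> 0).
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty applied in the update.
#' @param poly_power exponent of the polynomial learning-rate decay
#'   `lr * (1 - step/total)^power`; 0 disables decay.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early stopping: epochs without validation-loss improvement
#'   before training halts (>= 1).
#' @param seed RNG seed for shuffling, dropout and any weight init.
#' @param pretrain_rare_class warm up on tartar-containing scenes before the
#'   main loop (weight initialization aid for the rare class)?
#' @param pretrain_steps number of warm-up optimizer steps.
#' @param weights branch loss weights, see [cascade_weights()].
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, weight_decay = 1e-4,
                         poly_power = 0.9, batch_size = 4L, max_epochs = 60L,
                         patience = 20L, seed = 1L,
                         pretrain_rare_class = FALSE, pretrain_steps = 10L,
                         weights = cascade_weights()) {
  if (lr <= 0) stop("lr must be positive")
  if (patience < 1) stop("patience must be >= 1")
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 poly_power = poly_power, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 pretrain_rare_class = isTRUE(pretrain_rare_class),
                 pretrain_steps = as.integer(pretrain_steps),
                 weights = weights),
            class = "train_config")
}

#' Load image/mask samples referenced by a manifest
#' @param manifest data.frame from [make_dataset()] / [load_manifest()].
#' @param split one of `"train"`, `"val"`, `"test"`, or `NULL` for all rows.
#' @return list with parallel lists `images` and `masks`.
#' @export
load_samples <- function(manifest, split = NULL) {
  rows <- if (is.null(split)) manifest else manifest[manifest$split == split, ]
  list(images = lapply(rows$image, read_image),
       masks = lapply(rows$mask, read_mask),
       has_tartar = rows$has_tartar)
}

sgd_make_state <- function(params)
  lapply(params, function(p) array(0, dim(p$value) %||% length(p$value)))

sgd_step <- function(params, vel, lr, momentum, weight_decay) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    wd <- if (isTRUE(p$no_decay)) 0 else weight_decay
    g <- p$grad + wd * p$value
    vel[[i]] <- momentum * vel[[i]] + g
    p$value <- p$value - lr * vel[[i]]
  }
  vel
}

batch_loss_and_acc <- function(net, images, masks, idx, tc, training = TRUE) {
  x <- stack_images(images[idx])
  y <- stack_masks(masks[idx])
  out <- network_forward(net, x, training = training)
  loss <- cascade_loss(out, y, tc$weights)
  lg <- ag_value(out$final_logits)
  dm <- dim(lg)
  yd <- resize_mask_nearest(y, dm[1], dm[2])
  pred <- apply(lg, 4, function(a) max.col(matrix(a, ncol = dm[3]),
                                           ties.method = "first") - 1L)
  acc <- mean(pred == as.integer(yd))
  list(loss = loss, acc = acc)
}

# Re-estimate batch-norm running statistics with one full forward pass
# (momentum temporarily 1), so short training runs evaluate with statistics
# that match the training distribution.
recalibrate_bn <- function(net, images, tc) {
  bns <- nn_find(net, "batchnorm")
  for (b in bns) b$state$momentum <- 1
  on.exit(for (b in bns) b$state$momentum <- NULL)
  n <- length(images)
  take <- seq_len(min(n, max(tc$batch_size, 8L)))
  invisible(network_forward(net, stack_images(images[take]), training = TRUE))
}

#' Run a fixed number of SGD steps on in-memory data
#'
#' Low-level fitting loop used by [train_network()]; also convenient for
#' small-scale capability checks (e.g. overfitting a handful of scenes).
#'
#' @param net a [cascade_network()].
#' @param images,masks parallel lists of images (0..255) and integer masks.
#' @param steps number of optimizer steps.
#' @param tc a [train_config()].
#' @param total_steps horizon for the polynomial decay (defaults to `steps`).
#' @param step_offset steps already taken (continues the decay schedule).
#' @return final training pixel accuracy (at logit resolution), invisibly the
#'   per-step loss vector as attribute `"losses"`.
#' @export
sgd_fit <- function(net, images, masks, steps, tc = train_config(),
                    total_steps = steps, step_offset = 0L) {
  params <- nn_parameters(net)
  vel <- sgd_make_state(params)
  n <- length(images)
  losses <- numeric(steps)
  acc <- NA_real_
  with_seed_local(tc$seed + step_offset, {
    for (s in seq_len(steps)) {
      idx <- ((step_offset + s - 1L) * tc$batch_size + seq_len(tc$batch_size) - 1L) %% n + 1L
      frac <- min(1, (step_offset + s - 1L) / max(1L, total_steps))
      lr <- tc$lr * (1 - frac)^tc$poly_power
      res <- batch_loss_and_acc(net, images, masks, idx, tc, training = TRUE)
      losses[s] <- ag_value(res$loss)
      acc <- res$acc
      ag_zero_grad(params)
      ag_backward(res$loss)
      vel <- sgd_step(params, vel, lr, tc$momentum, tc$weight_decay)
    }
    recalibrate_bn(net, images, tc)
  })
  structure(acc, losses = losses)
}

#' Train a cascade segmentation network
#'
#' SGD with momentum, weight decay and polynomial learning-rate decay;
#' optional rare-class (tartar) warm-up; early stopping when the validation
#' loss has not improved for `patience` epochs; the best-on-validation state
#' is restored (and optionally checkpointed) at the end.
#'
#' @param config a [network_config()] or an already-built
#'   [cascade_network()].
#' @param manifest dataset manifest (or directory) with `train` and `val`
#'   splits, see [make_dataset()].
#' @param tc a [train_config()].
#' @param checkpoint optional path; the best model is saved there.
#' @param log_file optional CSV path for the per-epoch training log.
#' @return list with `net`, `log` (data.frame: epoch, lr, train_loss,
#'   train_acc, val_loss, val_acc), `best_epoch` and `checkpoint`.
#' @export
train_network <- function(config, manifest, tc = train_config(),
                          checkpoint = NULL, log_file = NULL) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  net <- if (inherits(config, "network_config")) cascade_network(config) else config
  train <- load_samples(manifest, "train")
  val <- load_samples(manifest, "val")
  if (length(train$images) == 0L || length(val$images) == 0L)
    stop("empty train or validation split")
  params <- nn_parameters(net)
  n <- length(train$images)
  steps_per_epoch <- max(1L, n %/% tc$batch_size)
  total_steps <- tc$max_epochs * steps_per_epoch
  log <- vector("list", tc$max_epochs)
  best <- list(loss = Inf, state = NULL, epoch = 0L)
  wait <- 0L

  with_seed_local(tc$seed, {
    if (tc$pretrain_rare_class && any(train$has_tartar)) {
      ridx <- which(train$has_tartar)
      sgd_fit(net, train$images[ridx], train$masks[ridx], tc$pretrain_steps,
              tc, total_steps = tc$pretrain_steps)
    }
    vel <- sgd_make_state(params)
    step <- 0L
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_acc <- 0; lr <- tc$lr
      for (b in seq_len(steps_per_epoch)) {
        idx <- ord[((b - 1L) * tc$batch_size) %% n + seq_len(tc$batch_size)]
        idx <- idx[!is.na(idx)]
        lr <- tc$lr * (1 - min(1, step / total_steps))^tc$poly_power
        res <- batch_loss_and_acc(net, train$images, train$masks, idx, tc,
                                  training = TRUE)
        ep_loss <- ep_loss + ag_value(res$loss)
        ep_acc <- ep_acc + res$acc
        ag_zero_grad(params)
        ag_backward(res$loss)
        vel <- sgd_step(params, vel, lr, tc$momentum, tc$weight_decay)
        step <- step + 1L
      }
      recalibrate_bn(net, train$images, tc)
      vres <- batch_loss_and_acc(net, val$images, val$masks,
                                 seq_along(val$images), tc, training = FALSE)
      vloss <- ag_value(vres$loss)
      log[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                 train_loss = ep_loss / steps_per_epoch,
                                 train_acc = ep_acc / steps_per_epoch,
                                 val_loss = vloss, val_acc = vres$acc)
      if (vloss < best$loss - 1e-8) {
        best <- list(loss = vloss, state = nn_state(net), epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tc$patience) break
      }
    }
  })
  if (!is.null(best$state)) nn_load_state(net, best$state)
  log <- do.call(rbind, log[!vapply(log, is.null, logical(1))])
  if (!is.null(log_file)) utils::write.csv(log, log_file, row.names = FALSE)
  if (!is.null(checkpoint)) save_checkpoint(net, checkpoint)
  list(net = net, log = log, best_epoch = best$epoch, checkpoint = checkpoint)
}

#' Evaluate a network on a dataset split, optionally across brightness levels
#'
#' Applies [brightness_scale()] to every image, runs inference, accumulates a
#' single confusion matrix over the split per brightness level and reports
#' pixel accuracy, mean IoU and macro F1.
#'
#' @param net a [cascade_network()] or checkpoint path.
#' @param manifest manifest data.frame, directory, or a
#'   `list(images=, masks=)` sample set.
#' @param split manifest split to use (ignored for sample lists).
#' @param brightness numeric vector of brightness factors.
#' @param json,csv optional report output paths.
#' @return data.frame with one row per brightness factor: `brightness`,
#'   `acc`, `miou`, `f1`, `n_images`, `n_pixels`; per-brightness confusion
#'   matrices attached as attribute `"confusion"`.
#' @export
evaluate_network <- function(net, manifest, split = "test",
                             brightness = c(0.7, 1.0, 1.3),
                             json = NULL, csv = NULL) {
  if (is.character(net)) net <- load_checkpoint(net)
  samples <- if (is.list(manifest) && !is.null(manifest$images)) manifest
             else load_samples(if (is.character(manifest)) load_manifest(manifest)
                               else manifest, split)
  if (length(samples$images) == 0L) stop("empty evaluation split")
  k <- net$config$num_classes
  rows <- list(); cms <- list()
  for (bf in brightness) {
    P <- matrix(0L, k, k)
    for (i in seq_along(samples$images)) {
      img <- brightness_scale(samples$images[[i]], bf)
      pred <- predict_mask(net, img)
      P <- P + confusion_matrix(pred, samples$masks[[i]], k)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      brightness = bf, acc = pixel_acc(P), miou = miou(P), f1 = f1(P),
      n_images = length(samples$images), n_pixels = sum(P))
    cms[[as.character(bf)]] <- P
  }
  report <- do.call(rbind, rows)
  if (!is.null(json))
    jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(csv)) utils::write.csv(report, csv, row.names = FALSE)
  attr(report, "confusion") <- cms
  report
}

#' Segment a single image file
#'
#' Reads an image, rescales it to the network's input size if needed, writes
#' the predicted class-id mask (and optionally a VOC-color overlay) as PNG.
#'
#' @param net a [cascade_network()] or checkpoint path.
#' @param image_path input PNG.
#' @param out_path output mask PNG (class ids as gray values).
#' @param overlay_path optional color overlay PNG.
#' @return the predicted integer mask, invisibly.
#' @export
predict_file <- function(net, image_path, out_path, overlay_path = NULL) {
  if (is.character(net)) net <- load_checkpoint(net)
  img <- read_image(image_path)
  size <- net$config$base_size
  if (!all(dim(img)[1:2] == size)) img <- resize_image_bilinear(img, size, size)
  mask <- predict_mask(net, img)
  write_mask(mask, out_path)
  if (!is.null(overlay_path)) write_image(overlay_mask(img, mask), overlay_path)
  invisible(mask)
}

#' Paired improved-vs-baseline comparison on identical data
#'
#' Trains the improved network and the unmodified baseline with identical
#' seeds and data, evaluates both on the same split, and returns a paired
#' table of synthetic-data metrics (not comparable to clinical results).
#'
#' @param manifest dataset manifest or directory.
#' @param config a [network_config()]; the baseline run sets
#'   `baseline_icnet = TRUE` on a copy.
#' @param tc a [train_config()].
#' @param split evaluation split.
#' @return data.frame with one row per model.
#' @export
compare_improved_vs_baseline <- function(manifest, config = network_config(),
                                         tc = train_config(), split = "test") {
  cfg_base <- config
  cfg_base$baseline_icnet <- TRUE
  cfg_base$use_cbam <- FALSE
  cfg_base$use_asymmetric <- FALSE
  out <- lapply(list(improved = config, baseline = cfg_base), function(cf) {
    fit <- train_network(cf, manifest, tc)
    ev <- evaluate_network(fit$net, manifest, split = split, brightness = 1.0)
    data.frame(acc = ev$acc, miou = ev$miou, f1 = ev$f1,
               parameters = nn_count_parameters(fit$net))
  })
  cbind(data.frame(model = names(out)), do.call(rbind, out))
}
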