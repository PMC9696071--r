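# Seeded generator of synthetic intraoral scenes with five-class masks.
#
# The generator emulates the *statistical* structure of a clinical intraoral
# photograph collection, not its photometry: bright tooth-like ellipses on a
# darker reddish oral background; four lesion classes painted as irregular
# blobs with a strongly imbalanced occurrence pattern (calculus and
# gingivitis common, worn surfaces intermediate, tartar rare); optional
# overexposure (right-shifted histogram); and additive sensor noise. Worn
# surfaces are deliberately rendered with low contrast against healthy tooth
# tissue — the hardest class to separate — while tartar is rare but
# high-contrast. Class ids: 0 background (including healthy teeth),
# 1 calculus, 2 gingivitis, 3 tartar, 4 worn surface.

LESION_CLASSES <- c(calculus = 1L, gingivitis = 2L, tartar = 3L, worn = 4L)

#' Scene specification
#'
#' Defaults reproduce the occurrence statistics of a 200-image clinical
#' collection with 209/215/33/100 occurrences of calculus, gingivitis, tartar
#' and worn surfaces: `lesion_mix` is the expected number of lesions of each
#' class per scene and lesion counts are Poisson, so tartar appears in about
#' 15% of scenes.
#'
#' @param seed integer RNG seed; every generated scene is a pure function of
#'   `(seed, spec)`.
#' @param size square image side in pixels (>= 32).
#' @param n_teeth integer range (length 2) of tooth count per scene.
#' @param lesion_mix named numeric vector: expected lesions per scene for
#'   calculus, gingivitis, tartar, worn.
#' @param class_imbalance multiplier on the tartar rate (1 keeps the
#'   reference rarity).
#' @param overexposed render an overexposed scene (gain 1.8 before noise)?
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(seed = 1L, size = 512L, n_teeth = c(4L, 7L),
                       lesion_mix = c(calculus = 209, gingivitis = 215,
                                      tartar = 33, worn = 100) / 200,
                       class_imbalance = 1, overexposed = FALSE,
                       noise_sigma = 5) {
  if (size < 32L) stop("size must be >= 32")
  if (any(lesion_mix < 0)) stop("lesion_mix rates must be non-negative")
  if (length(lesion_mix) != 4L) stop("lesion_mix needs 4 entries")
  names(lesion_mix) <- names(LESION_CLASSES)
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 n_teeth = as.integer(rep(n_teeth, length.out = 2)),
                 lesion_mix = lesion_mix, class_imbalance = class_imbalance,
                 overexposed = isTRUE(overexposed), noise_sigma = noise_sigma),
            class = "scene_spec")
}

# Band-limited noise field in [-1, 1]-ish range: coarse Gaussian grid,
# bilinearly upsampled.
smooth_noise <- function(h, w, cells = 8L) {
  ch <- max(2L, cells); cw <- max(2L, cells)
  coarse <- array(stats::rnorm(ch * cw), c(ch, cw, 1L))
  resize_image_bilinear(coarse, h, w)[, , 1]
}

# Irregular blob membership: radius-modulated ellipse around (cy, cx).
blob_mask <- function(size, cy, cx, r0, aspect = 1) {
  k1 <- sample(2:4, 1); k2 <- sample(5:7, 1)
  a1 <- stats::runif(1, 0.15, 0.35); a2 <- stats::runif(1, 0.05, 0.2)
  p1 <- stats::runif(1, 0, 2 * pi); p2 <- stats::runif(1, 0, 2 * pi)
  ys <- matrix(seq_len(size), size, size) - cy
  xs <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  th <- atan2(xs, ys * aspect)
  rr <- sqrt(ys^2 * aspect^2 + xs^2)
  rmax <- r0 * (1 + a1 * sin(k1 * th + p1) + a2 * sin(k2 * th + p2))
  rr <= rmax
}

ellipse_mask <- function(size, cy, cx, ry, rx, rot = 0) {
  ys <- matrix(seq_len(size), size, size) - cy
  xs <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  u <- ys * cos(rot) + xs * sin(rot)
  v <- -ys * sin(rot) + xs * cos(rot)
  (u / ry)^2 + (v / rx)^2 <= 1
}

paint <- function(img, region, rgb, jitter = 0) {
  n <- sum(region)
  if (n == 0) return(img)
  for (c in 1:3) {
    ch <- img[, , c]
    ch[region] <- rgb[c] + if (jitter > 0) stats::rnorm(n, 0, jitter) else 0
    img[, , c] <- ch
  }
  img
}

#' Generate one synthetic intraoral scene
#'
#' Deterministic per `(seed, spec)`: the same spec yields a bit-identical
#' image/mask pair on every call.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (`size x size x 3` integer array, 0..255) and
#'   `mask` (`size x size` integer matrix, class ids 0..4).
#' @export
generate_scene <- function(spec = scene_spec()) {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec")
  size <- spec$size
  with_seed_local(spec$seed, {
    # oral background: dark reddish tissue with low-frequency texture
    img <- array(0, c(size, size, 3L))
    tex <- smooth_noise(size, size, 8L)
    base <- c(108, 56, 52)
    for (c in 1:3) img[, , c] <- base[c] + 14 * tex + 4 * stats::rnorm(size * size)

    # teeth: bright ellipses along a shallow arc (class 0 like the background)
    nt <- if (spec$n_teeth[1] == spec$n_teeth[2]) spec$n_teeth[1]
          else sample(spec$n_teeth[1]:spec$n_teeth[2], 1)
    tooth <- matrix(FALSE, size, size)
    centers <- vector("list", nt)
    for (i in seq_len(nt)) {
      fx <- (i - 0.5) / nt
      cx <- size * (0.1 + 0.8 * fx)
      cy <- size * (0.42 + 0.1 * sin(pi * fx)) + stats::rnorm(1, 0, size * 0.015)
      rx <- size * stats::runif(1, 0.06, 0.085)
      ry <- size * stats::runif(1, 0.12, 0.16)
      rot <- stats::rnorm(1, 0, 0.12)
      em <- ellipse_mask(size, cy, cx, ry, rx, rot)
      tooth <- tooth | em
      centers[[i]] <- list(cy = cy, cx = cx, ry = ry, rx = rx)
    }
    shade <- smooth_noise(size, size, 6L)
    tooth_col <- c(226, 216, 192)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[tooth] <- tooth_col[c] + (10 * shade + 5 * stats::rnorm(size * size))[tooth]
      img[, , c] <- ch
    }

    mask <- matrix(0L, size, size)
    rates <- spec$lesion_mix
    rates["tartar"] <- rates["tartar"] * spec$class_imbalance
    counts <- stats::rpois(4L, rates)
    names(counts) <- names(LESION_CLASSES)
    if (sum(counts) == 0L && sum(rates) > 0) {
      # collected lesion photographs always contain at least one lesion
      counts[sample.int(4L, 1, prob = rates)] <- 1L
    }

    place_on_tooth <- function(margin = FALSE) {
      ct <- centers[[sample(nt, 1)]]
      if (margin) {
        list(cy = ct$cy + ct$ry * stats::runif(1, 0.6, 1.0),
             cx = ct$cx + stats::rnorm(1, 0, ct$rx * 0.4))
      } else {
        list(cy = ct$cy + stats::rnorm(1, 0, ct$ry * 0.4),
             cx = ct$cx + stats::rnorm(1, 0, ct$rx * 0.4))
      }
    }

    for (cls in names(LESION_CLASSES)) {
      for (rep_i in seq_len(counts[[cls]])) {
        id <- LESION_CLASSES[[cls]]
        if (cls == "calculus") {
          # yellow-brown deposit at the tooth margin
          at <- place_on_tooth(margin = TRUE)
          bm <- blob_mask(size, at$cy, at$cx, size * stats::runif(1, 0.08, 0.12))
          region <- bm & (tooth | mask == 0L)
          img <- paint(img, region, c(184, 150, 92), jitter = 7)
        } else if (cls == "gingivitis") {
          # reddened inflamed band where gum meets a tooth
          at <- place_on_tooth(margin = TRUE)
          bm <- blob_mask(size, at$cy + size * 0.02, at$cx,
                          size * stats::runif(1, 0.08, 0.13), aspect = 1.8)
          region <- bm & !tooth
          img <- paint(img, region, c(168, 52, 58), jitter = 6)
        } else if (cls == "tartar") {
          # rare but high-contrast textured deposit
          at <- place_on_tooth(margin = TRUE)
          bm <- blob_mask(size, at$cy, at$cx, size * stats::runif(1, 0.07, 0.11))
          region <- bm
          img <- paint(img, region, c(148, 128, 96), jitter = 22)
        } else {
          # worn surface: low-contrast flattened highlight, close to tooth color
          at <- place_on_tooth(margin = FALSE)
          bm <- blob_mask(size, at$cy, at$cx, size * stats::runif(1, 0.09, 0.14))
          region <- bm & tooth
          img <- paint(img, region, c(234, 226, 206), jitter = 3)
        }
        mask[region] <- id
      }
    }

    if (spec$overexposed) img <- clip255(img * 1.8)
    if (spec$noise_sigma > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sigma), dim(img))
    list(image = round_half_up(clip255(img)), mask = mask)
  })
}

#' Augment an image/mask pair
#'
#' Random crop (side fraction 0.6-1.0) restored to the original size
#' (bilinear for the image, nearest neighbor for the mask), horizontal flip
#' with probability 0.5, and +-20% brightness/contrast/saturation jitter.
#' Deterministic per seed; class ids are preserved.
#'
#' @param image `H x W x 3` array in 0..255.
#' @param mask integer `H x W` class-id matrix.
#' @param seed RNG seed.
#' @return list with transformed `image` and `mask`.
#' @export
augment <- function(image, mask, seed = 1L) {
  dm <- dim(image)
  with_seed_local(seed, {
    f <- stats::runif(1, 0.6, 1.0)
    ch <- max(1L, round(dm[1] * f)); cw <- max(1L, round(dm[2] * f))
    oy <- sample.int(dm[1] - ch + 1L, 1); ox <- sample.int(dm[2] - cw + 1L, 1)
    img <- image[oy:(oy + ch - 1L), ox:(ox + cw - 1L), , drop = FALSE]
    msk <- mask[oy:(oy + ch - 1L), ox:(ox + cw - 1L), drop = FALSE]
    img <- resize_image_bilinear(img, dm[1], dm[2])
    msk <- resize_mask_nearest(msk, dm[1], dm[2])
    if (stats::runif(1) < 0.5) {
      img <- img[, rev(seq_len(dm[2])), , drop = FALSE]
      msk <- msk[, rev(seq_len(dm[2])), drop = FALSE]
    }
    img <- img * stats::runif(1, 0.8, 1.2)                      # brightness
    mu <- mean(img)
    img <- (img - mu) * stats::runif(1, 0.8, 1.2) + mu          # contrast
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    sf <- stats::runif(1, 0.8, 1.2)                             # saturation
    for (c in 1:3) img[, , c] <- gray + (img[, , c] - gray) * sf
    list(image = clip255(img), mask = msk)
  })
}

#' Overexpose an image
#'
#' Multiplies intensities by `gain` and clips at 255, shifting the histogram
#' to the right (toward saturation) as in an overexposed intraoral
#' photograph.
#'
#' @param image `H x W x 3` array in 0..255.
#' @param gain multiplicative gain (>= 1; 1 is the identity).
#' @export
overexpose <- function(image, gain = 1.8) {
  if (gain < 1) stop("gain must be >= 1")
  clip255(image * gain)
}

#' Linear brightness scaling
#'
#' Multiplies intensities by `factor` and clips to 0..255; the
#' brightness-robustness evaluation uses factors 0.7, 1.0 and 1.3.
#'
#' @param image `H x W x 3` array in 0..255.
#' @param factor brightness factor (> 0).
#' @export
brightness_scale <- function(image, factor = 1) {
  if (factor <= 0) stop("factor must be positive")
  clip255(image * factor)
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes `images/scene_XXXX.png` and `masks/scene_XXXX.png` under `dir`,
#' splits scenes into train/val/test and records everything in
#' `manifest.csv`. Scenes whose mask contains tartar (the rare class) are
#' replicated `oversample_rare` times in the *training* manifest only.
#'
#' @param n number of distinct scenes.
#' @param spec a [scene_spec()]; scene `i` uses seed `spec$seed + i - 1`.
#' @param dir output directory (created if needed).
#' @param split train/val/test fractions summing to 1 (default 0.7/0.2/0.1).
#' @param oversample_rare training replication factor for tartar scenes.
#' @return the manifest `data.frame` (columns `image`, `mask`, `split`,
#'   `has_tartar`, `scene_seed`), invisibly also written to
#'   `dir/manifest.csv`.
#' @export
make_dataset <- function(n, spec = scene_spec(), dir = tempfile("lesions"),
                         split = c(0.7, 0.2, 0.1), oversample_rare = 1L) {
  if (abs(sum(split) - 1) > 1e-8 || length(split) != 3L)
    stop("split must be three fractions summing to 1")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  counts <- diff(round(cumsum(c(0, split)) * n))
  splits <- rep(c("train", "val", "test"), counts)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    scene <- generate_scene(sp)
    img_path <- file.path(dir, "images", sprintf("scene_%04d.png", i))
    mask_path <- file.path(dir, "masks", sprintf("scene_%04d.png", i))
    write_image(scene$image, img_path)
    write_mask(scene$mask, mask_path)
    rows[[i]] <- data.frame(image = img_path, mask = mask_path,
                            split = splits[i],
                            has_tartar = any(scene$mask == LESION_CLASSES[["tartar"]]),
                            scene_seed = sp$seed)
  }
  manifest <- do.call(rbind, rows)
  if (oversample_rare > 1L) {
    extra <- manifest[manifest$split == "train" & manifest$has_tartar, ]
    if (nrow(extra) > 0)
      manifest <- rbind(manifest,
                        extra[rep(seq_len(nrow(extra)), oversample_rare - 1L), ])
  }
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "dir") <- dir
  invisible(manifest)
}

#' Load a dataset manifest written by [make_dataset()]
#' @param dir dataset directory containing `manifest.csv`.
#' @return the manifest `data.frame`.
#' @export
load_manifest <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "manifest.csv") else dir
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(manifest, "dir") <- dirname(path)
  manifest
}
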