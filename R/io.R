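# PNG I/O for images and class masks.
#
# Masks are stored as 8-bit grayscale PNGs whose pixel values are the raw
# class indices (the decoded content of a VOC-style indexed PNG); this round
# trips exactly through the `png` package, which cannot emit palette chunks.
# `voc_palette()` provides the standard VOC colors for rendering masks as RGB
# overlays.

#' Read / write an 8-bit RGB image
#'
#' @param path PNG file path.
#' @return `read_image`: numeric `H x W x 3` array with values in 0..255.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' @rdname read_image
#' @param image numeric `H x W x 3` array in 0..255.
#' @export
write_image <- function(image, path) {
  png::writePNG(clip01(round_half_up(image) / 255), path)
  invisible(path)
}

#' Read / write a class mask
#'
#' @param path PNG file path.
#' @return `read_mask`: integer `H x W` matrix of class ids.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' @rdname read_mask
#' @param mask integer matrix of class ids (0..255).
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Standard VOC color map
#'
#' The PASCAL VOC bit-interleaving palette; class 0 is black, classes 1-4 are
#' maroon, green, olive and navy.
#'
#' @param n number of entries.
#' @return `n x 3` integer matrix of RGB values in 0..255.
#' @export
voc_palette <- function(n = 5L) {
  pal <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    id <- i - 1L
    r <- g <- b <- 0L
    for (j in 0:7) {
      r <- bitwOr(r, bitwShiftL(bitwAnd(id, 1L), 7L - j))
      g <- bitwOr(g, bitwShiftL(bitwAnd(bitwShiftR(id, 1L), 1L), 7L - j))
      b <- bitwOr(b, bitwShiftL(bitwAnd(bitwShiftR(id, 2L), 1L), 7L - j))
      id <- bitwShiftR(id, 3L)
    }
    pal[i, ] <- c(r, g, b)
  }
  colnames(pal) <- c("r", "g", "b")
  pal
}

#' Render a class mask in VOC palette colors
#'
#' @param mask integer `H x W` matrix of class ids.
#' @param n_classes palette size.
#' @return `H x W x 3` array in 0..255.
#' @export
colorize_mask <- function(mask, n_classes = max(mask) + 1L) {
  pal <- voc_palette(max(n_classes, max(mask) + 1L))
  out <- array(0, c(dim(mask), 3L))
  for (c in 1:3) out[, , c] <- pal[mask + 1L, c]
  out
}

#' Blend an image with a colorized mask for inspection
#'
#' @param image `H x W x 3` array in 0..255.
#' @param mask integer `H x W` class-id matrix.
#' @param alpha mask opacity on lesion pixels.
#' @return `H x W x 3` array in 0..255.
#' @export
overlay_mask <- function(image, mask, alpha = 0.5) {
  col <- colorize_mask(mask)
  w <- array(rep(as.numeric(mask > 0) * alpha, 3L), dim(col))
  image * (1 - w) + col * w
}
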