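# Automatic color equalization (ACE) for overexposed intraoral photographs.
#
# ACE corrects a channel by, for every pixel p, summing the saturated slope
# of its brightness difference to the other pixels j, weighted by inverse
# spatial distance:
#
#   Rc(p) = sum_{j != p} r(I(p) - I(j)) / d(p, j)
#
# with r(x) = clip(x / T, -1, 1) (an odd, bounded slope function) and d the
# Euclidean pixel distance. A second step linearly restores Rc to the [0, 255]
# dynamic range. Because Rc depends on brightness *differences* only, the
# result is exactly invariant to a global additive brightness offset.

#' ACE parameters
#'
#' @param slope_threshold positive saturation threshold `T` of the slope
#'   function: differences beyond `T` contribute the full +-1.
#' @param neighborhood `"global"` (all pixel pairs), `"auto"` (global for
#'   images up to 64x64, square window of radius 31 otherwise), or an integer
#'   window radius in pixels.
#' @param distance_kind distance metric for `d(p, j)`; only `"euclidean"` is
#'   implemented.
#' @param per_channel apply the adjustment to each RGB channel independently?
#' @return an object of class `ace_params`.
#' @export
ace_params <- function(slope_threshold = 20, neighborhood = "auto",
                       distance_kind = "euclidean", per_channel = TRUE) {
  if (!is.numeric(slope_threshold) || length(slope_threshold) != 1 ||
      !is.finite(slope_threshold) || slope_threshold <= 0)
    stop("invalid parameter: slope_threshold must be a positive number")
  if (is.numeric(neighborhood)) {
    if (neighborhood < 1) stop("invalid parameter: radius must be >= 1")
    neighborhood <- as.integer(neighborhood)
  } else {
    neighborhood <- match.arg(neighborhood, c("auto", "global"))
  }
  distance_kind <- match.arg(distance_kind, "euclidean")
  structure(list(slope_threshold = slope_threshold, neighborhood = neighborhood,
                 distance_kind = distance_kind, per_channel = isTRUE(per_channel)),
            class = "ace_params")
}

#' Saturated slope function of ACE
#'
#' The odd, bounded response `r(x) = clip(x / T, -1, 1)`: linear for small
#' brightness differences, saturating at +-1 beyond the threshold.
#'
#' @param x numeric vector of brightness differences.
#' @param T positive saturation threshold.
#' @return values in `[-1, 1]`.
#' @export
saturation_r <- function(x, T) {
  if (!is.numeric(T) || length(T) != 1 || !is.finite(T) || T <= 0)
    stop("invalid parameter: T must be a positive number")
  pmin(pmax(x / T, -1), 1)
}

resolve_radius <- function(channel, params) {
  nb <- params$neighborhood
  if (is.numeric(nb)) return(as.integer(nb))
  if (identical(nb, "global")) return(0L)
  if (max(dim(channel)) <= 64L) 0L else 31L
}

#' Chromatic/spatial adjustment (first ACE step)
#'
#' Computes the unnormalized adjustment `Rc` for one channel. Depends only on
#' pixel differences, so adding a constant to the channel leaves `Rc`
#' unchanged. A 1x1 image yields `Rc = 0` (empty sum).
#'
#' @param channel numeric matrix (one image channel, nominally 0..255).
#' @param params an [ace_params()] object.
#' @return an `ace_intermediate`: list with the `Rc` matrix and the radius
#'   actually used (0 = global).
#' @export
chromatic_spatial_adjust <- function(channel, params = ace_params()) {
  if (!is.matrix(channel) || length(channel) < 1)
    stop("channel must be a non-empty numeric matrix")
  radius <- resolve_radius(channel, params)
  rc <- if (length(channel) == 1L) {
    matrix(0, 1, 1)
  } else {
    ace_rc_cpp(channel, params$slope_threshold, radius)
  }
  structure(list(Rc = rc, radius = radius), class = "ace_intermediate")
}

#' Dynamic-range restoration (second ACE step)
#'
#' Linearly maps `Rc` onto `[0, 255]` (order preserving). A constant `Rc`
#' maps to mid-gray 127.5; rounding to integers happens only at the end of
#' [ace()].
#'
#' @param inter an `ace_intermediate` from [chromatic_spatial_adjust()], or a
#'   plain numeric matrix of `Rc` values.
#' @return numeric matrix with values in `[0, 255]`.
#' @export
dynamic_range_restore <- function(inter) {
  rc <- if (inherits(inter, "ace_intermediate")) inter$Rc else inter
  if (!all(is.finite(rc))) stop("Rc must be finite")
  lo <- min(rc); hi <- max(rc)
  if (hi - lo <= .Machine$double.eps * max(abs(lo), abs(hi), 1))
    return(array(127.5, dim(rc)))
  (rc - lo) / (hi - lo) * 255
}

round_half_up <- function(x) floor(x + 0.5)

#' ACE automatic color equalization
#'
#' Applies the two ACE steps to each channel of an RGB image and rounds
#' half-up to 8-bit integers at the very end. The mapping is exactly
#' invariant to a global additive brightness offset of the input (the first
#' step uses only pixel differences) and equivariant to channel permutation
#' when `per_channel` is `TRUE`.
#'
#' @param image numeric `H x W x 3` array, nominally in 0..255 (values are
#'   not clipped on input).
#' @param params an [ace_params()] object.
#' @return `H x W x 3` array of integers in 0..255.
#' @export
ace <- function(image, params = ace_params()) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("ace expects an H x W x 3 RGB array")
  out <- array(0, dim(image))
  if (params$per_channel) {
    for (c in 1:3) {
      inter <- chromatic_spatial_adjust(image[, , c], params)
      out[, , c] <- dynamic_range_restore(inter)
    }
  } else {
    lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
    inter <- chromatic_spatial_adjust(lum, params)
    restored <- dynamic_range_restore(inter)
    for (c in 1:3) out[, , c] <- restored
  }
  round_half_up(pmin(pmax(out, 0), 255))
}
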