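# Small shared helpers.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
clip255 <- function(x) pmin(pmax(x, 0), 255)

# Batch a list of (H, W, C) arrays into an (H, W, C, N) array.
stack_images <- function(images) {
  if (is.array(images) && length(dim(images)) == 4L) return(images)
  if (is.array(images) && length(dim(images)) == 3L)
    return(array(images, c(dim(images), 1L)))
  dm <- dim(images[[1]])
  out <- array(0, c(dm, length(images)))
  for (i in seq_along(images)) out[, , , i] <- images[[i]]
  out
}

# Batch a list of (H, W) masks into an (H, W, N) integer array.
stack_masks <- function(masks) {
  if (is.matrix(masks)) return(array(masks, c(dim(masks), 1L)))
  if (is.array(masks) && length(dim(masks)) == 3L) return(masks)
  dm <- dim(masks[[1]])
  out <- array(0L, c(dm, length(masks)))
  for (i in seq_along(masks)) out[, , i] <- masks[[i]]
  out
}

# Nearest-neighbor resize of an integer mask (H, W) or stack (H, W, N).
resize_mask_nearest <- function(mask, out_h, out_w) {
  dm <- dim(mask)
  ih <- pmin(dm[1], floor((seq_len(out_h) - 0.5) * dm[1] / out_h) + 1L)
  iw <- pmin(dm[2], floor((seq_len(out_w) - 0.5) * dm[2] / out_w) + 1L)
  if (length(dm) == 2L) mask[ih, iw, drop = FALSE]
  else mask[ih, iw, , drop = FALSE]
}

# Bilinear resize of a plain (H, W, C) image array.
resize_image_bilinear <- function(img, out_h, out_w) {
  dm <- dim(img)
  array(bilinear_fwd_cpp(as.numeric(img), dm[1], dm[2], dm[3], 1L,
                         as.integer(out_h), as.integer(out_w)),
        c(out_h, out_w, dm[3]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
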