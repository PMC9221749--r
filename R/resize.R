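# Image resizing. Bilinear interpolation is separable, so a resize is two
# small matrix products: out = A %*% img %*% t(B), where A and B hold the
# per-axis interpolation weights (half-pixel-centre convention, edges
# clamped). Masks use nearest-neighbour so they stay binary.

resize_weights <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_in))
  # centre of output pixel i maps to input coordinate (i + .5) * n_in / n_out - .5
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  lo <- floor(src)
  frac <- src - lo
  i0 <- pmin(pmax(lo, 0), n_in - 1) + 1
  i1 <- pmin(pmax(lo + 1, 0), n_in - 1) + 1
  a <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  a[cbind(idx, i0)] <- a[cbind(idx, i0)] + (1 - frac)
  a[cbind(idx, i1)] <- a[cbind(idx, i1)] + frac
  a
}

nearest_index <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  pmin(pmax(round(src), 0), n_in - 1) + 1
}

#' Bilinear image resize
#'
#' Half-pixel-centre sampling with clamped edges (the convention used by
#' common imaging libraries when corner alignment is off). Intended for
#' intensity images and probability maps.
#'
#' @param x Matrix or (H, W, C) array.
#' @param height,width Output extent.
#' @return Resized matrix or array of the same channel count.
#' @export
resize_bilinear <- function(x, height, width) {
  nd <- length(dim(x))
  if (!nd %in% c(2, 3)) stop("x must be a matrix or 3-D array")
  if (dim(x)[1] == height && dim(x)[2] == width) return(x * 1)
  a <- resize_weights(dim(x)[1], height)
  b <- t(resize_weights(dim(x)[2], width))
  if (nd == 2) return(a %*% x %*% b)
  out <- array(0, c(height, width, dim(x)[3]))
  for (c in seq_len(dim(x)[3])) out[, , c] <- a %*% x[, , c] %*% b
  out
}

#' Nearest-neighbour image resize
#'
#' Used for masks: output values are drawn from the input, so binary
#' inputs stay binary.
#'
#' @inheritParams resize_bilinear
#' @export
resize_nearest <- function(x, height, width) {
  nd <- length(dim(x))
  if (!nd %in% c(2, 3)) stop("x must be a matrix or 3-D array")
  if (dim(x)[1] == height && dim(x)[2] == width) return(x)
  ri <- nearest_index(dim(x)[1], height)
  ci <- nearest_index(dim(x)[2], width)
  if (nd == 2) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}
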