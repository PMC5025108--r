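#' Convert an RGB image to grayscale luminance
#'
#' Uses the ITU-R BT.601 luma weights `0.299 R + 0.587 G + 0.114 B`, which
#' sum to 1 so the result stays in `[0, 1]`.
#'
#' @param rgb A `height x width x 3` numeric array with channels in `[0, 1]`.
#' @return A numeric matrix in `[0, 1]`.
#' @export
to_grayscale <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L) {
    stop("to_grayscale() expects a height x width x 3 array")
  }
  0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
}

#' Laplacian-of-Gaussian kernel
#'
#' Builds the "Mexican hat" kernel
#' \deqn{LoG(x, y) = -\frac{1}{\pi\sigma^4}
#'   \left[1 - \frac{x^2+y^2}{2\sigma^2}\right]
#'   e^{-\frac{x^2+y^2}{2\sigma^2}}}
#' on a square support of side `2 * radius + 1`. With the leading minus the
#' centre is the kernel minimum and the surrounding ring positive, so
#' convolving a dark blob on a bright background yields a strong positive
#' response at the blob centre. The zero-crossing ring sits at radius
#' `sigma * sqrt(2)`; `sigma` should be matched to the blob scale (a
#' sperm head of ~6 px across at 40x magnification on a 480x640 frame
#' corresponds to the default `sigma = 2`).
#'
#' @param sigma Gaussian scale in pixels (> 0).
#' @param radius Half-width of the square support in pixels (>= 1); the
#'   default `ceiling(3 * sigma)` captures essentially all kernel mass.
#' @return A `(2*radius+1)` square numeric matrix.
#' @export
log_kernel <- function(sigma = 2, radius = ceiling(3 * sigma)) {
  stopifnot(sigma > 0, radius >= 1)
  off <- -radius:radius
  r2 <- outer(off^2, off^2, `+`)
  -(1 / (pi * sigma^4)) * (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
}

#' Laplacian-of-Gaussian blob enhancement
#'
#' Convolves the frame with [log_kernel()] under mirror (reflect) border
#' padding, then rescales the response affinely to `[0, 1]` (minimum to 0,
#' maximum to 1). The rescaled response is the stimulus `S` fed to the ICM
#' network: dark compact blobs (sperm heads) map to the highest stimulus so
#' their pixel neurons fire first.
#'
#' A constant input has a constant (near-zero-sum) response; its degenerate
#' rescaling is defined to return 0.5 everywhere.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @inheritParams log_kernel
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
apply_log <- function(image, sigma = 2, radius = ceiling(3 * sigma)) {
  validate_gray(image)
  k <- log_kernel(sigma, radius)
  if (nrow(image) < nrow(k) || ncol(image) < ncol(k)) {
    stop("image (", nrow(image), "x", ncol(image),
         ") is smaller than the LoG kernel (", nrow(k), "x", ncol(k), ")")
  }
  rescale_unit(convolve2d_reflect(image, k))
}

#' Affine rescaling to the unit interval
#'
#' @param x Numeric matrix.
#' @return `(x - min) / (max - min)`; all 0.5 if `x` is constant.
#' @keywords internal
rescale_unit <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) {
    return(array(0.5, dim = dim(x)))
  }
  (x - lo) / (hi - lo)
}

# 2-D convolution (kernel flipped) with mirror padding, same-size output.
# Accumulates one shifted slice of the padded image per kernel entry; for
# the kernel sizes used here (<= 13x13) this is fast enough in plain R.
convolve2d_reflect <- function(image, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(image)
  nc <- ncol(image)
  if (nr <= kr || nc <= kc) stop("image too small for mirror padding")
  ridx <- c(rev(seq_len(kr) + 1L), seq_len(nr), nr - seq_len(kr))
  cidx <- c(rev(seq_len(kc) + 1L), seq_len(nc), nc - seq_len(kc))
  pad <- image[ridx, cidx]
  out <- matrix(0, nr, nc)
  for (a in -kr:kr) {
    for (b in -kc:kc) {
      kv <- kernel[a + kr + 1L, b + kc + 1L]
      if (kv == 0) next
      # convolution: out(i,j) += k(a,b) * pad(i - a, j - b) (pad offset kr,kc)
      out <- out + kv * pad[(kr + 1L - a):(kr + nr - a),
                            (kc + 1L - b):(kc + nc - b)]
    }
  }
  out
}
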