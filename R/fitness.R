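#' Fitness configuration for the mutual-information objective
#'
#' The optimizer drives the mutual information (MI) between the original
#' grayscale frame and the candidate binary segmentation toward a fixed
#' target. The target 0.07 bits corresponds to the information content of a
#' correct head mask: roughly sixty heads of ~40 px on a 480x640 frame give
#' a foreground fraction near 1%, whose binary entropy -- an upper bound on
#' the MI -- is about 0.07 bits, and a head-aligned mask nearly attains the
#' bound because head pixels occupy distinctly dark intensity bins.
#' [mi_target_from_truth()] recomputes the constant from any annotated
#' frame.
#'
#' @param mi_target Target mutual information in bits (default 0.07).
#' @param intensity_bins Number of equal-width intensity bins for the
#'   grayscale image over `[0, 1]` (default 256, the native 8-bit
#'   resolution).
#' @param tolerance Termination tolerance on the fitness error in bits
#'   (default 0.005, half the target's last printed digit -- the search has
#'   "met" the target once the MI rounds to it): the swarm stops once the
#'   best error falls to or below it.
#' @return A `fitness_config` list.
#' @export
fitness_config <- function(mi_target = 0.07, intensity_bins = 256,
                           tolerance = 0.005) {
  stopifnot(mi_target > 0, intensity_bins >= 2, tolerance >= 0)
  structure(list(mi_target = mi_target,
                 intensity_bins = as.integer(intensity_bins),
                 tolerance = tolerance),
            class = "fitness_config")
}

#' Marginal entropy of a histogram
#'
#' \eqn{H = -\sum_b \rho_b \log_2 \rho_b} over bins with positive mass
#' (`0 log 0` is taken as 0). Result in bits, within
#' `[0, log2(length(p))]`.
#'
#' @param p Vector of relative frequencies summing to 1.
#' @return Entropy in bits.
#' @export
marginal_entropy <- function(p) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Quantise intensities into equal-width bins over [0, 1]
#'
#' @param x Numeric matrix or vector in `[0, 1]`.
#' @param bins Number of bins.
#' @return Integer bin indices in `1..bins` (value 1 falls in the top bin).
#' @export
quantize_intensity <- function(x, bins = 256) {
  pmin(as.integer(floor(x * bins)) + 1L, as.integer(bins))
}

#' Joint entropy of a quantised image and a binary mask
#'
#' Entropy (bits) of the joint relative-frequency table of (intensity bin,
#' mask value). Satisfies `max(H(X), H(Y)) <= H(X,Y) <= H(X) + H(Y)`.
#'
#' @param xq Integer matrix of bin indices (from [quantize_intensity()]).
#' @param y 0/1 mask of the same shape.
#' @param bins Number of intensity bins used for `xq`.
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(xq, y, bins = 256) {
  if (length(xq) != length(y)) {
    stop("image and mask must have the same shape")
  }
  counts <- tabulate(as.integer(xq) + as.integer(bins) * as.integer(y),
                     nbins = 2L * bins)
  marginal_entropy(counts[counts > 0] / length(xq))
}

#' Mutual information between a grayscale image and a binary mask
#'
#' `MI = H(X) + H(Y) - H(X, Y)` in bits, where `X` is the image quantised
#' into `bins` equal-width intensity bins over `[0, 1]` and `Y` the mask.
#' Non-negative (up to rounding) and bounded by `min(H(X), H(Y))`.
#'
#' @param x Grayscale matrix in `[0, 1]`, or a pre-quantised integer matrix
#'   (pass `quantized = TRUE` to skip re-binning).
#' @param y 0/1 mask of the same shape.
#' @param bins Number of intensity bins (default 256).
#' @param quantized Set `TRUE` when `x` already holds bin indices.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y, bins = 256, quantized = FALSE) {
  if (length(x) != length(y)) stop("image and mask must have the same shape")
  xq <- if (quantized) as.integer(x) else quantize_intensity(x, bins)
  n <- length(xq)
  cx <- tabulate(xq, nbins = bins)
  hy_counts <- c(sum(y == 0), sum(y == 1))
  hx <- marginal_entropy(cx[cx > 0] / n)
  hy <- marginal_entropy(hy_counts[hy_counts > 0] / n)
  hxy <- joint_entropy(xq, y, bins)
  hx + hy - hxy
}

#' Fitness error of a candidate segmentation
#'
#' Absolute deviation of the achieved mutual information from the target;
#' the particle swarm minimises this quantity.
#'
#' @param mi Mutual information in bits (>= 0).
#' @param config [fitness_config()] (only `mi_target` is used).
#' @return `|mi - mi_target|`.
#' @export
fitness_error <- function(mi, config = fitness_config()) {
  abs(mi - config$mi_target)
}

#' Derive the MI target from an annotated frame
#'
#' Computes the mutual information between a frame and its ground-truth head
#' mask -- the data-driven way to obtain the fitness target for a new imaging
#' setup.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param truth_mask 0/1 ground-truth mask of the same shape.
#' @param bins Number of intensity bins.
#' @return Mutual information in bits.
#' @export
mi_target_from_truth <- function(image, truth_mask, bins = 256) {
  mutual_information(image, truth_mask, bins = bins)
}
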