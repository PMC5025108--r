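#' Label connected foreground regions of a binary mask
#'
#' Partitions the mask's 1-pixels into maximal connected components under
#' 4- or 8-connectivity (compiled flood fill; labels assigned in order of
#' each region's first pixel in column-major scan order).
#'
#' @param mask 0/1 matrix.
#' @param connectivity 4 or 8 (default 8: sperm heads are compact blobs and
#'   8-connectivity avoids splitting anti-aliased edges).
#' @return A list of regions, each a list with `label`, `pixels` (two-column
#'   matrix of 1-based (row, col) coordinates), `area`, `centroid`
#'   (row, col means) and `touches_border` (any pixel on the outermost
#'   row/column).
#' @export
label_regions <- function(mask, connectivity = 8) {
  validate_mask(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- region_label_cpp(mask, as.integer(connectivity))
  fg <- which(lab > 0L)
  if (length(fg) == 0L) return(list())
  row <- ((fg - 1L) %% nr) + 1L
  col <- ((fg - 1L) %/% nr) + 1L
  groups <- split(seq_along(fg), lab[fg])
  regions <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    px <- cbind(row = row[idx], col = col[idx])
    regions[[k]] <- list(
      label = k,
      pixels = px,
      area = nrow(px),
      centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
      touches_border = any(px[, 1] == 1L | px[, 1] == nr |
                             px[, 2] == 1L | px[, 2] == nc)
    )
  }
  regions
}

#' Discard regions near the image border
#'
#' Segments touching the border band are neglected to prevent incorrect
#' detections from partially visible cells. A region is removed when any of
#' its pixels lies within `margin` pixels of an image edge (with `margin =
#' 1`, the outermost pixel row/column). `margin = 0` removes nothing.
#' Idempotent.
#'
#' @param regions List of regions from [label_regions()].
#' @param shape Integer vector `(height, width)` of the source mask.
#' @param margin Border band width in pixels (default 1).
#' @return The filtered region list.
#' @export
filter_border <- function(regions, shape, margin = 1) {
  stopifnot(margin >= 0)
  if (margin == 0) return(regions)
  keep <- vapply(regions, function(r) {
    !any(r$pixels[, 1] <= margin | r$pixels[, 1] > shape[1] - margin |
           r$pixels[, 2] <= margin | r$pixels[, 2] > shape[2] - margin)
  }, logical(1))
  regions[keep]
}

#' Discard regions below a minimum area
#'
#' Opt-in area guard; the detector's primary debris rejection is
#' intensity-based (see [filter_dark_regions()]), so the default pipeline
#' leaves this off.
#'
#' @param regions List of regions from [label_regions()].
#' @param min_area Minimum pixel count to keep (0 keeps everything).
#' @return The filtered region list.
#' @export
filter_min_area <- function(regions, min_area = 0) {
  if (min_area <= 0) return(regions)
  regions[vapply(regions, function(r) r$area >= min_area, logical(1))]
}

#' Keep only regions with a head-dark core
#'
#' Sperm heads are the darkest structures in a phase-contrast frame; debris,
#' tail fragments and noise specks are brighter. A region is kept when its
#' darkest pixels (the `core_quantile` quantile of its original-frame
#' intensities) fall below a threshold placed `split` of the way from the
#' frame's dark reference (the `dark_quantile` intensity quantile,
#' essentially the head-core level) up to the background level (the frame
#' median). This is the detector's debris elimination: it separates heads
#' from debris by their different intensity values rather than by size or
#' shape.
#'
#' @param regions List of regions from [label_regions()].
#' @param image The original grayscale frame the mask was segmented from.
#' @param split Fractional position of the acceptance threshold between the
#'   dark reference and the background level (default 1/3).
#' @param core_quantile Quantile of a region's intensities that must clear
#'   the threshold (default 0, the region minimum).
#' @param dark_quantile Frame quantile defining the dark reference
#'   (default 0.002, about the darkest 600 px of a 480x640 frame).
#' @return The filtered region list.
#' @export
filter_dark_regions <- function(regions, image, split = 1/3,
                                core_quantile = 0, dark_quantile = 0.002) {
  if (length(regions) == 0L) return(regions)
  thr <- dark_core_threshold(image, split, dark_quantile)
  nr <- nrow(image)
  keep <- vapply(regions, function(r) {
    v <- image[(r$pixels[, 2] - 1L) * nr + r$pixels[, 1]]
    stats::quantile(v, core_quantile, names = FALSE) <= thr
  }, logical(1))
  regions[keep]
}

dark_core_threshold <- function(image, split = 1/3, dark_quantile = 0.002) {
  dark <- stats::quantile(image, dark_quantile, names = FALSE)
  bg <- stats::median(image)
  dark + split * (bg - dark)
}

#' Refine a raw pulse mask into the segmentation output
#'
#' The feature-level cleanup applied to the ICM pulse image: connected
#' regions are labelled, border-touching regions and regions without a
#' head-dark core are discarded, and the surviving regions are reassembled
#' into a mask. This refined mask is the detector's segmentation output and
#' is also what the tuning fitness scores (see [segment_frame()]).
#'
#' Implemented directly on the compiled label matrix so it is cheap enough
#' to sit inside the optimizer's objective.
#'
#' @param mask Raw 0/1 pulse mask.
#' @param image Original grayscale frame.
#' @param connectivity 4 or 8 (default 8).
#' @param border_margin Border band in pixels (default 1).
#' @param split,core_quantile,dark_quantile See [filter_dark_regions()];
#'   `threshold` overrides the derived intensity threshold (used to fix it
#'   once per frame).
#' @param threshold Absolute intensity threshold for the region core, or
#'   `NULL` to derive it from the frame.
#' @param min_area Optional minimum region area (default 0, off).
#' @return A 0/1 matrix containing only the kept regions.
#' @export
refine_mask <- function(mask, image, connectivity = 8, border_margin = 1,
                        split = 1/3, core_quantile = 0,
                        dark_quantile = 0.002, threshold = NULL,
                        min_area = 0) {
  stopifnot(all(dim(mask) == dim(image)))
  nr <- nrow(mask)
  nc <- ncol(mask)
  if (is.null(threshold)) {
    threshold <- dark_core_threshold(image, split, dark_quantile)
  }
  if (core_quantile <= 0) {
    # hot path (used inside the optimizer's objective): one compiled pass
    return(refine_mask_cpp(mask, image, as.integer(connectivity),
                           as.integer(border_margin), threshold,
                           as.integer(min_area)))
  }
  lab <- region_label_cpp(mask, as.integer(connectivity))
  nlab <- max(lab)
  if (nlab == 0L) return(mask * 0)
  fg <- which(lab > 0L)
  labs <- lab[fg]
  drop <- logical(nlab)
  if (border_margin > 0) {
    m <- border_margin
    band <- c(lab[c(seq_len(m), nr - seq_len(m) + 1L), ],
              lab[, c(seq_len(m), nc - seq_len(m) + 1L)])
    drop[unique(band[band > 0L])] <- TRUE
  }
  core <- if (core_quantile <= 0) {
    vapply(split.default(image[fg], labs), min, numeric(1))
  } else {
    vapply(split.default(image[fg], labs),
           stats::quantile, numeric(1), probs = core_quantile, names = FALSE)
  }
  drop[as.integer(names(core))[core > threshold]] <- TRUE
  if (min_area > 0) {
    areas <- tabulate(labs, nbins = nlab)
    drop[areas < min_area & areas > 0L] <- TRUE
  }
  out <- matrix(0, nr, nc)
  keep_fg <- fg[!drop[labs]]
  out[keep_fg] <- 1
  out
}

#' Region centroids
#'
#' The arithmetic mean of each region's pixel rows and columns -- the
#' detected sperm-head (nucleus) location.
#'
#' @param regions List of regions from [label_regions()].
#' @return A two-column matrix (row, col), one row per region; zero rows if
#'   `regions` is empty.
#' @export
centroids <- function(regions) {
  if (length(regions) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("row", "col"))))
  }
  out <- t(vapply(regions, function(r) r$centroid, numeric(2)))
  colnames(out) <- c("row", "col")
  out
}

#' Match predicted detections to ground-truth locations
#'
#' Greedy one-to-one nearest-neighbour matching: candidate pairs within the
#' matching radius are accepted in order of increasing distance, ties broken
#' by the truth point's row-major order and then the prediction's order.
#' `matched + missed = nrow(truth)` and `matched + spurious =
#' nrow(predicted)`.
#'
#' @param predicted Two-column matrix of predicted (row, col) centroids.
#' @param truth Two-column matrix of true (row, col) locations.
#' @param radius Matching radius in pixels: a scalar, or a vector with one
#'   entry per truth row (e.g. each head's semi-major axis).
#' @return A list with `matched`, `missed`, `spurious` counts and `pairs`, a
#'   two-column matrix of (predicted index, truth index) for each match.
#' @export
match_detections <- function(predicted, truth, radius) {
  stopifnot(all(radius > 0))
  np <- NROW(predicted)
  nt <- NROW(truth)
  if (length(radius) == 1L) radius <- rep(radius, nt)
  stopifnot(length(radius) == nt)
  if (np == 0L || nt == 0L) {
    return(list(matched = 0L, missed = nt, spurious = np,
                pairs = matrix(integer(0), ncol = 2)))
  }
  predicted <- as.matrix(predicted)
  truth <- as.matrix(truth)
  d <- sqrt(outer(predicted[, 1], truth[, 1], `-`)^2 +
              outer(predicted[, 2], truth[, 2], `-`)^2)
  cand <- which(d <= rep(radius, each = np), arr.ind = TRUE)
  if (nrow(cand) > 0L) {
    truth_rank <- order(truth[, 1], truth[, 2])
    trank <- match(seq_len(nt), truth_rank)
    ord <- order(d[cand], trank[cand[, 2]], cand[, 1])
    cand <- cand[ord, , drop = FALSE]
  }
  used_p <- logical(np)
  used_t <- logical(nt)
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("predicted", "truth")))
  for (k in seq_len(nrow(cand))) {
    i <- unname(cand[k, 1])
    j <- unname(cand[k, 2])
    if (!used_p[i] && !used_t[j]) {
      used_p[i] <- TRUE
      used_t[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  list(matched = sum(used_t), missed = sum(!used_t),
       spurious = sum(!used_p), pairs = pairs)
}
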