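#' Read a microscopy frame as a grayscale intensity matrix
#'
#' Reads an 8- or 16-bit PNG or TIFF frame and returns a numeric matrix of
#' intensities in `[0, 1]` (pixel values divided by the bit-depth maximum;
#' the `png`/`tiff` readers perform that scaling). Three-channel images are
#' converted with [to_grayscale()]; an alpha channel, if present, is dropped.
#'
#' @param path Path to a PNG or TIFF file.
#' @return A numeric matrix with values in `[0, 1]`, rows indexing image rows
#'   top to bottom.
#' @seealso [read_mask()], [write_mask()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: file does not exist: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path,
         " (expected png or tiff)")
  )
  if (length(x) == 0L) stop("zero-sized image: ", path)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
    if (dim(x)[3] == 3L) {
      x <- to_grayscale(x)
    } else if (dim(x)[3] == 1L) {
      x <- x[, , 1L]
    } else {
      stop("unsupported channel count (", dim(x)[3], ") in ", path)
    }
  }
  if (!is.matrix(x)) stop("could not interpret ", path, " as a 2-D image")
  validate_gray(x)
  x
}

#' Write a grayscale image to PNG or TIFF
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param path Output path; format chosen by extension (.png, .tif/.tiff).
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  validate_gray(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = 8L),
    stop("unsupported output format '", ext, "'")
  )
  invisible(path)
}

#' Write a binary segmentation mask as an 8-bit PNG
#'
#' Foreground pixels (value 1) are written as 255, background (0) as 0, so
#' the file is viewable in any image viewer and round-trips bit-exactly
#' through [read_mask()].
#'
#' @param mask Matrix of 0/1 values.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask)
  storage.mode(mask) <- "double"
  png::writePNG(mask, path)
  invisible(path)
}

#' Read a binary mask PNG
#'
#' Inverse of [write_mask()]: any pixel above half intensity is foreground.
#'
#' @param path PNG path.
#' @return Numeric 0/1 matrix.
#' @export
read_mask <- function(path) {
  x <- read_image(path)
  (x > 0.5) + 0
}

#' Write detected head centroids to CSV
#'
#' Writes a CSV with header `id,row,col`. Coordinates in the file are
#' 0-based (row 0 is the top image row, increasing downward), the common
#' convention of image-processing toolchains; the in-package representation
#' is R's 1-based matrix indexing, so 1 is subtracted on write and added
#' back by [read_centroids()].
#'
#' @param centroids Two-column matrix (row, col) of 1-based coordinates, one
#'   row per detection, or `NULL`/zero-row matrix for none.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_centroids <- function(centroids, path) {
  if (is.null(centroids) || NROW(centroids) == 0L) {
    df <- data.frame(id = integer(), row = numeric(), col = numeric())
  } else {
    centroids <- as.matrix(centroids)
    stopifnot(ncol(centroids) == 2L)
    df <- data.frame(
      id = seq_len(nrow(centroids)),
      row = centroids[, 1] - 1,
      col = centroids[, 2] - 1
    )
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a centroid CSV written by [write_centroids()]
#'
#' @param path CSV path.
#' @return Two-column matrix of 1-based (row, col) coordinates.
#' @export
read_centroids <- function(path) {
  df <- utils::read.csv(path)
  cbind(row = df$row + 1, col = df$col + 1)
}

#' Write an evaluation report as JSON
#'
#' Serialises the list returned by [evaluate_batch()] (or any metrics list)
#' with scalar values unboxed and full numeric precision.
#'
#' @param report A list (e.g. from [evaluate_batch()]).
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "string")
  invisible(path)
}

# ---- internal validators -------------------------------------------------

validate_gray <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("image must be a numeric matrix")
  }
  if (nrow(x) < 3L || ncol(x) < 3L) {
    stop("image must be at least 3x3 (the ICM link kernel needs a 3x3 ",
         "neighbourhood); got ", nrow(x), "x", ncol(x))
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 1) {
    stop("image intensities must lie in [0, 1] with no missing values")
  }
  invisible(x)
}

validate_mask <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("mask must be a numeric matrix")
  if (!all(x == 0 | x == 1)) stop("mask values must be exactly 0 or 1")
  invisible(x)
}
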