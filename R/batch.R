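#' Segment a batch of frame files
#'
#' Runs [segment_frame()] on each input image and writes, per frame, the
#' segmentation mask (`<name>_mask.png`), the detected centroids
#' (`<name>_centroids.csv`) and the tuned parameters with the convergence
#' trace (`<name>_params.json`). A frame that fails is logged and skipped.
#'
#' @param paths Character vector of input image paths (PNG/TIFF).
#' @param out_dir Output directory (created if missing).
#' @param ... Arguments passed on to [segment_frame()].
#' @param quiet Suppress per-frame progress messages.
#' @return Invisibly, a data frame with one row per input: `path`, `ok`,
#'   `n_detections`, `fitness`, `seconds`.
#' @export
segment_files <- function(paths, out_dir, ..., quiet = FALSE) {
  if (length(paths) == 0L) stop("no input images given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    p <- paths[k]
    stem <- tools::file_path_sans_ext(basename(p))
    t0 <- Sys.time()
    res <- tryCatch(segment_frame(read_image(p), ...), error = identity)
    secs <- as.numeric(Sys.time() - t0, units = "secs")
    if (inherits(res, "error")) {
      message("segmentation failed for ", p, ": ", conditionMessage(res))
      rows[[k]] <- data.frame(path = p, ok = FALSE, n_detections = NA_integer_,
                              fitness = NA_real_, seconds = secs)
      next
    }
    write_mask(res$mask, file.path(out_dir, paste0(stem, "_mask.png")))
    write_centroids(res$centroids,
                    file.path(out_dir, paste0(stem, "_centroids.csv")))
    jsonlite::write_json(
      list(params = list(f = res$params$f, g = res$params$g,
                         h = res$params$h, n = res$params$n_iterations,
                         e_init = res$params$e_init),
           fitness = res$optimization$best_fitness,
           mutual_information = res$optimization$best_mi,
           evaluations = res$optimization$evaluations_used,
           convergence_trace = res$optimization$convergence_trace),
      file.path(out_dir, paste0(stem, "_params.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    if (!quiet) {
      message(sprintf("%s: %d detections (fitness %.4f, %.1fs)", basename(p),
                      nrow(res$centroids), res$optimization$best_fitness,
                      secs))
    }
    rows[[k]] <- data.frame(path = p, ok = TRUE,
                            n_detections = nrow(res$centroids),
                            fitness = res$optimization$best_fitness,
                            seconds = secs)
  }
  out <- do.call(rbind, rows)
  if (!any(out$ok)) stop("segmentation failed for every input image")
  invisible(out)
}

#' Evaluate predicted mask files against ground-truth mask files
#'
#' Pairs the two file lists positionally after sorting each by name, reads
#' every mask with [read_mask()] and scores the batch with
#' [evaluate_batch()]. List lengths must match; mismatches are reported with
#' the offending names.
#'
#' @param pred_paths Predicted mask files (PNG).
#' @param truth_paths Ground-truth mask files (PNG), same length.
#' @return The [evaluate_batch()] report, with file names attached to the
#'   per-image table.
#' @export
evaluate_mask_files <- function(pred_paths, truth_paths) {
  pred_paths <- sort(pred_paths)
  truth_paths <- sort(truth_paths)
  if (length(pred_paths) != length(truth_paths)) {
    stop("unpaired mask files: ", length(pred_paths), " predicted vs ",
         length(truth_paths), " truth")
  }
  if (length(pred_paths) == 0L) stop("no mask files given")
  pairs <- Map(function(p, t) {
    list(predicted = read_mask(p), truth = read_mask(t))
  }, pred_paths, truth_paths)
  report <- evaluate_batch(unname(pairs))
  report$per_image$predicted <- basename(pred_paths)
  report$per_image$truth <- basename(truth_paths)
  report
}

#' Write a batch of synthetic frames with ground truth to disk
#'
#' For each seed writes `image_<seed>.png`, `mask_<seed>.png` and
#' `centroids_<seed>.csv` into `out_dir`.
#'
#' @param spec [scene_spec()].
#' @param seeds Integer vector of scene seeds.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the vector of image paths written.
#' @export
write_synthetic_batch <- function(spec = scene_spec(), seeds = 1:5,
                                  out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(seeds))
  for (k in seq_along(seeds)) {
    scene <- generate_scene(spec, seed = seeds[k])
    paths[k] <- file.path(out_dir, sprintf("image_%d.png", seeds[k]))
    write_image(scene$image, paths[k])
    write_mask(scene$mask, file.path(out_dir,
                                     sprintf("mask_%d.png", seeds[k])))
    write_centroids(scene$centroids,
                    file.path(out_dir,
                              sprintf("centroids_%d.csv", seeds[k])))
  }
  invisible(paths)
}
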