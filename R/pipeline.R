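#' Segment one frame end to end
#'
#' The full detector: grayscale conversion (if needed), Laplacian-of-Gaussian
#' blob enhancement, per-frame PSO tuning of the four ICM parameters against
#' the mutual-information fitness, and feature extraction. Each candidate
#' pulse image is refined by [refine_mask()] (border rejection plus
#' intensity-based debris elimination, with the intensity threshold fixed
#' once per frame) before it is scored, so the fitness evaluates -- and the
#' function returns -- the detector's actual segmentation output. Set
#' `refine = FALSE` to tune and return raw pulse images instead.
#'
#' @param image Grayscale matrix in `[0, 1]`, or an RGB array.
#' @param log_sigma,log_radius LoG scale and support (see [apply_log()]).
#' @param swarm [swarm_config()]; set its `seed` for reproducible runs.
#' @param fitness [fitness_config()].
#' @param connectivity Component connectivity, 4 or 8 (default 8).
#' @param border_margin Border band in pixels for region rejection
#'   (default 1).
#' @param refine Apply [refine_mask()] to candidate masks (default TRUE).
#' @param split,core_quantile,dark_quantile Intensity-rejection settings,
#'   see [filter_dark_regions()].
#' @param min_area Optional minimum region area (default 0, off).
#' @return A list: `mask` (0/1 segmentation output), `regions` (its region
#'   list), `centroids` (matrix of detections), `params` (tuned
#'   [icm_params()]), `optimization` (full [tune_icm()] result) and
#'   `stimulus` (the LoG response).
#' @export
segment_frame <- function(image, log_sigma = 2,
                          log_radius = ceiling(3 * log_sigma),
                          swarm = swarm_config(), fitness = fitness_config(),
                          connectivity = 8, border_margin = 1,
                          refine = TRUE, split = 1/3, core_quantile = 0,
                          dark_quantile = 0.002, min_area = 0) {
  if (length(dim(image)) == 3L) image <- to_grayscale(image)
  validate_gray(image)
  s <- apply_log(image, sigma = log_sigma, radius = log_radius)
  mask_filter <- NULL
  if (isTRUE(refine)) {
    thr <- dark_core_threshold(image, split, dark_quantile)
    mask_filter <- function(mask) {
      refine_mask(mask, image, connectivity = connectivity,
                  border_margin = border_margin,
                  core_quantile = core_quantile, threshold = thr,
                  min_area = min_area)
    }
  }
  opt <- tune_icm(image, s, swarm = swarm, fitness = fitness,
                  mask_filter = mask_filter)
  mask <- opt$best_mask
  regions <- label_regions(mask, connectivity = connectivity)
  if (!isTRUE(refine)) {
    regions <- filter_border(regions, dim(mask), margin = border_margin)
    regions <- filter_min_area(regions, min_area)
  }
  list(mask = mask, regions = regions, centroids = centroids(regions),
       params = opt$best_params, optimization = opt, stimulus = s)
}

#' Run the detector on seeded synthetic frames and score it
#'
#' Generates `length(scene_seeds)` synthetic frames from `spec`, segments
#' each with [segment_frame()], scores the predicted masks against the
#' generated ground truth with [evaluate_batch()], and matches detected
#' centroids to the planted heads (matching radius: each head's semi-major
#' axis, i.e. half its major axis).
#'
#' @param spec [scene_spec()] describing the frames.
#' @param scene_seeds Integer vector; one frame is generated per seed.
#' @param pso_seed Seed for the particle swarm (the same for every frame).
#' @param ... Further arguments passed to [segment_frame()].
#' @return A list: `evaluation` (from [evaluate_batch()]), `detection` (data
#'   frame per frame: planted, matched, missed, spurious, pairs_planted,
#'   pairs_resolved), `head_recovery` (overall fraction of planted heads
#'   matched), `pair_resolution` (overall fraction of agglutinated pairs
#'   resolved into two matched heads, `NaN` if none planted) and `frames`
#'   (per-frame [segment_frame()] results).
#' @export
run_benchmark <- function(spec = scene_spec(), scene_seeds = 1:5,
                          pso_seed = 1, ...) {
  frames <- vector("list", length(scene_seeds))
  pairs <- vector("list", length(scene_seeds))
  det_rows <- vector("list", length(scene_seeds))
  for (k in seq_along(scene_seeds)) {
    scene <- generate_scene(spec, seed = scene_seeds[k])
    sw <- swarm_config(seed = pso_seed)
    res <- segment_frame(scene$image, swarm = sw, ...)
    pairs[[k]] <- list(predicted = res$mask, truth = scene$mask)

    m <- match_detections(res$centroids, scene$centroids,
                          radius = scene$heads$major)
    pr <- pair_resolution_counts(m, scene$heads)
    det_rows[[k]] <- data.frame(
      frame = k, planted = nrow(scene$heads), matched = m$matched,
      missed = m$missed, spurious = m$spurious,
      pairs_planted = pr["planted"], pairs_resolved = pr["resolved"],
      row.names = NULL
    )
    frames[[k]] <- list(scene = scene, result = res, match = m)
  }
  detection <- do.call(rbind, det_rows)
  list(
    evaluation = evaluate_batch(pairs),
    detection = detection,
    head_recovery = sum(detection$matched) / max(1, sum(detection$planted)),
    pair_resolution = if (sum(detection$pairs_planted) == 0) NaN else
      sum(detection$pairs_resolved) / sum(detection$pairs_planted),
    frames = frames
  )
}

# how many agglutinated pairs had both member heads matched by distinct
# detections (one-to-one matching makes the detections distinct)
pair_resolution_counts <- function(match, heads) {
  pair_ids <- unique(heads$pair[!is.na(heads$pair)])
  if (length(pair_ids) == 0L) {
    return(c(planted = 0L, resolved = 0L))
  }
  matched_truth <- match$pairs[, 2]
  resolved <- vapply(pair_ids, function(pid) {
    members <- which(heads$pair == pid)
    all(members %in% matched_truth)
  }, logical(1))
  c(planted = length(pair_ids), resolved = sum(resolved))
}
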