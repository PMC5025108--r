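#' Pixel-level confusion counts between predicted and true masks
#'
#' True positives are predicted foreground pixels that are truly head
#' pixels; false negatives measure under-segmentation, false positives
#' over-segmentation. The four counts always sum to the pixel count.
#'
#' @param predicted 0/1 predicted mask.
#' @param truth 0/1 ground-truth mask of the same shape.
#' @return A list with integer `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(predicted, truth) {
  validate_mask(predicted)
  validate_mask(truth)
  if (!all(dim(predicted) == dim(truth))) {
    stop("predicted and truth masks must have the same shape")
  }
  tp <- sum(predicted == 1 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Segmentation metrics from confusion counts
#'
#' \itemize{
#'   \item accuracy = (TP + TN) / (TP + TN + FP + FN)
#'   \item sensitivity (TP rate) = TP / (TP + FN)
#'   \item specificity = TN / (TN + FP)
#'   \item precision (positive predictive value) = TP / (TP + FP)
#' }
#' A metric whose denominator is zero is reported as `NaN` with a warning,
#' never silently as 0.
#'
#' @param counts List with `tp`, `tn`, `fp`, `fn` (from [confusion()]).
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, each in `[0, 1]` when defined.
#' @export
seg_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero")
  ratio <- function(num, den, name) {
    if (den == 0) {
      warning(name, " is undefined (zero denominator); reporting NaN")
      return(NaN)
    }
    num / den
  }
  c(accuracy = (tp + tn) / total,
    sensitivity = ratio(tp, tp + fn, "sensitivity"),
    specificity = ratio(tn, tn + fp, "specificity"),
    precision = ratio(tp, tp + fp, "precision"))
}

#' Evaluate a batch of predicted/truth mask pairs
#'
#' Computes the four metrics per image, their unweighted mean across images
#' (the headline aggregate), and pooled-count metrics (counts summed over
#' all images before forming the ratios). Mean and pooled aggregates differ
#' whenever images have unequal foreground, so both are reported.
#'
#' @param pairs Non-empty list; each element a list with elements
#'   `predicted` and `truth` (0/1 masks of matching shape).
#' @return A list with `per_image` (data frame of counts and metrics),
#'   `mean` (named vector) and `pooled` (named vector).
#' @export
evaluate_batch <- function(pairs) {
  if (length(pairs) == 0L) stop("evaluate_batch() needs at least one pair")
  rows <- lapply(seq_along(pairs), function(i) {
    cc <- confusion(pairs[[i]]$predicted, pairs[[i]]$truth)
    m <- seg_metrics(cc)
    data.frame(image = i, tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
               accuracy = m["accuracy"], sensitivity = m["sensitivity"],
               specificity = m["specificity"], precision = m["precision"],
               row.names = NULL)
  })
  per_image <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "sensitivity", "specificity", "precision")
  mean_metrics <- colMeans(per_image[metric_cols])
  pooled_counts <- list(tp = sum(per_image$tp), tn = sum(per_image$tn),
                        fp = sum(per_image$fp), fn = sum(per_image$fn))
  list(per_image = per_image,
       mean = mean_metrics,
       pooled = seg_metrics(pooled_counts))
}
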