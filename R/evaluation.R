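#' Confusion-matrix diagnostic metrics
#'
#' Sensitivity, specificity, positive and negative predictive values, and
#' accuracy (all in percent) from paired predicted and true labels. Rates
#' whose denominator is zero are reported as `NA` rather than 0.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive The label treated as positive.
#' @return One-row tibble: tp, fp, tn, fn, sensitivity, specificity, ppv,
#'   npv, accuracy.
#' @export
#' @examples
#' confusion_metrics(c("a", "a", "b"), c("a", "b", "b"), positive = "a")
confusion_metrics <- function(predicted, truth, positive) {
  if (length(predicted) == 0 || length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must be equal-length and non-empty.",
          class = "lesioncam_input_error")
  }
  pp <- predicted == positive
  tp_ <- truth == positive
  tp <- sum(pp & tp_); fp <- sum(pp & !tp_)
  tn <- sum(!pp & !tp_); fn <- sum(!pp & tp_)
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 ppv = rate(tp, tp + fp),
                 npv = rate(tn, tn + fn),
                 accuracy = rate(tp + tn, tp + fp + tn + fn))
}

#' ROC curve and AUC
#'
#' Builds the ROC curve over all unique score thresholds and integrates the
#' area by the trapezoidal rule, which is exactly the pairwise concordance
#' probability with ties counted one half. Outputs from several
#' cross-validation folds are pooled by concatenating their score and label
#' vectors before calling this function.
#'
#' @param scores Numeric scores for the positive class.
#' @param labels True labels.
#' @param positive The label treated as positive.
#' @return A `roc_result`: list with `points` (tibble: threshold, fpr, tpr,
#'   starting at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_curve_auc <- function(scores, labels, positive) {
  if (any(!is.finite(scores))) {
    abort("Scores must be finite.", class = "lesioncam_input_error")
  }
  y <- labels == positive
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both classes must be present to define the ROC curve.",
          class = "lesioncam_input_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  # collapse tied scores so each threshold is crossed once
  grp <- cumsum(!duplicated(s))
  tp_cum <- cumsum(yy); fp_cum <- cumsum(!yy)
  last_of_grp <- !duplicated(grp, fromLast = TRUE)
  thr <- s[last_of_grp]
  tpr <- c(0, tp_cum[last_of_grp] / n_pos)
  fpr <- c(0, fp_cum[last_of_grp] / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  points <- tibble::tibble(threshold = c(Inf, thr), fpr = fpr, tpr = tpr)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC ", signif(x$auc, 4), " (", x$n_pos, " positive, ",
      x$n_neg, " negative)\n", sep = "")
  invisible(x)
}

#' Extract the activated region from a normalized CAM
#'
#' Binarizes at a fraction of the map maximum (default 0.5) and keeps the
#' largest 8-connected component; an all-zero map yields an empty region.
#'
#' @param cam A normalized `cam_map` (typically upsampled to image
#'   resolution) or a matrix in \[0,1\].
#' @param threshold Fraction of the maximum used for binarization.
#' @return Logical matrix: the activated region.
#' @export
localize_from_cam <- function(cam, threshold = 0.5) {
  m <- if (inherits(cam, "cam_map")) {
    if (!cam$normalized) {
      abort("CAM must be normalized before localization.",
            class = "lesioncam_contract_error")
    }
    cam$values
  } else cam
  if (min(m) < 0 || max(m) > 1 + 1e-9) {
    abort("CAM must be normalized before localization.",
          class = "lesioncam_contract_error")
  }
  mx <- max(m)
  if (mx == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  bin <- m >= threshold * mx
  lab <- .label_components8(bin)
  if (max(lab) == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Overlap ratio between activated region and truth mask
#'
#' Intersection over union. Two empty regions count as perfect agreement
#' (correct non-activation on a lesion-free image); an empty region against a
#' non-empty one (or vice versa) scores 0. An intersection-over-truth
#' variant is available via `method = "iot"`.
#'
#' @param region Logical activated region.
#' @param truth Logical truth mask of the same shape.
#' @param method `"iou"` (default) or `"iot"`.
#' @return Overlap in \[0, 1\].
#' @export
overlap_ratio <- function(region, truth, method = c("iou", "iot")) {
  method <- match.arg(method)
  region <- as_logical_mask(region)
  truth <- as_logical_mask(truth)
  if (!all(dim(region) == dim(truth))) {
    abort("Region and truth shapes differ.", class = "lesioncam_input_error")
  }
  a <- sum(region); t <- sum(truth)
  if (a == 0 && t == 0) return(1)
  if (a == 0 || t == 0) return(0)
  inter <- sum(region & truth)
  if (method == "iou") inter / sum(region | truth) else inter / t
}

#' Fraction of images correctly localized at an overlap cutoff
#'
#' @param overlaps Numeric vector of overlap ratios, or a tibble with an
#'   `overlap` column (as produced by [localization_scores()]).
#' @param cutoff Overlap cutoff (default 0.5).
#' @return Fraction of results with `overlap >= cutoff`.
#' @export
correct_ratio <- function(overlaps, cutoff = 0.5) {
  if (is.data.frame(overlaps)) overlaps <- overlaps$overlap
  if (length(overlaps) == 0) {
    abort("No localization results supplied.", class = "lesioncam_input_error")
  }
  mean(overlaps >= cutoff)
}

#' Score CAM-based lesion localization over a set of images
#'
#' For each lesion image: compute the Grad-CAM for its true class, normalize,
#' upsample to image resolution, extract the activated region, and measure
#' its overlap with the truth mask.
#'
#' @param model A `cam_cnn` model.
#' @param images List of `labeled_image` with lesion masks.
#' @param class_fun Function mapping an image's `class_label` to the model
#'   class used as the CAM target; defaults to the identity.
#' @param cam_threshold Binarization fraction for [localize_from_cam()].
#' @param cutoff Overlap cutoff for the `correct` flag.
#' @param overlap_method `"iou"` or `"iot"`.
#' @return Tibble: image_id, overlap, correct.
#' @export
localization_scores <- function(model, images, class_fun = identity,
                                cam_threshold = 0.5, cutoff = 0.5,
                                overlap_method = "iou") {
  purrr::map_dfr(images, function(im) {
    if (is.null(im$lesion_mask)) {
      abort(sprintf("Image '%s' has no truth mask.", im$image_id),
            class = "lesioncam_input_error")
    }
    cam <- compute_cam(model, im, class_fun(im$class_label))
    up <- upsample_cam(normalize_cam(cam), dim(im$lesion_mask))
    region <- localize_from_cam(up, threshold = cam_threshold)
    ov <- overlap_ratio(region, im$lesion_mask, method = overlap_method)
    tibble::tibble(image_id = im$image_id, overlap = ov,
                   correct = ov >= cutoff)
  })
}

#' Total number of evaluated images across cross-validation groups
#'
#' `n_groups * per_group_test_size + n_extra`, where `n_extra` counts
#' held-out images tested in addition to the rotating test folds.
#'
#' @param n_groups Number of cross-validation groups.
#' @param per_group_test_size Fixed test-set size per group.
#' @param n_extra Extra held-out images.
#' @return Total image count.
#' @export
#' @examples
#' evaluation_totals(5, 300, 90) # depth task
#' evaluation_totals(5, 660, 90) # detection task
evaluation_totals <- function(n_groups, per_group_test_size, n_extra = 0L) {
  stopifnot(n_groups >= 0, per_group_test_size >= 0, n_extra >= 0)
  n_groups * per_group_test_size + n_extra
}
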