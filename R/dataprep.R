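#' Quality thresholds for image filtering
#'
#' Frames whose high-frequency content is too low (motion blur / defocus) or
#' whose near-saturated fraction is too high (halation) are excluded.
#' `quality_thresholds(blur_min = 0, halation_max = 1)` disables filtering.
#'
#' @param blur_min Exclude images with `blur_score` strictly below this.
#' @param halation_max Exclude images with `halation_fraction` strictly above
#'   this.
#' @export
quality_thresholds <- function(blur_min = 1e-5, halation_max = 0.30) {
  if (!is.finite(blur_min) || !is.finite(halation_max)) {
    abort("Quality thresholds must be finite.",
          class = "lesioncam_parameter_error")
  }
  list(blur_min = blur_min, halation_max = halation_max)
}

#' Image quality scores
#'
#' `blur_score` is the variance of a discrete Laplacian of the luminance
#' channel (low for defocused or motion-blurred frames); `halation_fraction`
#' is the fraction of pixels with all three channels >= 0.98.
#'
#' @param image A `labeled_image` or an H x W x 3 array in \[0,1\].
#' @param thresholds A [quality_thresholds()] list.
#' @return One-row tibble: image_id, blur_score, halation_fraction, excluded,
#'   reasons (comma-separated subset of `"blur"`, `"halation"`).
#' @export
quality_scores <- function(image, thresholds = quality_thresholds()) {
  iid <- NA_character_
  if (inherits(image, "labeled_image")) {
    iid <- image$image_id
    image <- image$pixels
  }
  if (!is.array(image) || length(dim(image)) != 3 || any(dim(image) == 0)) {
    abort("`image` must be a non-empty H x W x 3 array.",
          class = "lesioncam_input_error")
  }
  y <- luminance(image)
  n <- nrow(y); m <- ncol(y)
  if (n < 3 || m < 3) {
    lap <- 0
  } else {
    core <- y[2:(n - 1), 2:(m - 1)]
    lap <- y[1:(n - 2), 2:(m - 1)] + y[3:n, 2:(m - 1)] +
      y[2:(n - 1), 1:(m - 2)] + y[2:(n - 1), 3:m] - 4 * core
  }
  blur_score <- if (length(lap) > 1) var(as.vector(lap)) else 0
  halation_fraction <- mean(image[, , 1] >= 0.98 &
                              image[, , 2] >= 0.98 &
                              image[, , 3] >= 0.98)
  reasons <- c(if (blur_score < thresholds$blur_min) "blur",
               if (halation_fraction > thresholds$halation_max) "halation")
  tibble::tibble(image_id = iid, blur_score = blur_score,
                 halation_fraction = halation_fraction,
                 excluded = length(reasons) > 0,
                 reasons = paste(reasons, collapse = ","))
}

#' Filter a cohort by image quality
#'
#' @param cohort A `lesion_cohort`.
#' @param thresholds A [quality_thresholds()] list.
#' @return List with `cohort` (retained images), `exclusions` (tibble of
#'   removed images with reasons) and `report` (quality tibble for every
#'   input image). Retained plus excluded always equals the input.
#' @export
filter_images <- function(cohort, thresholds = quality_thresholds()) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  report <- purrr::map_dfr(cohort$images, quality_scores, thresholds = thresholds)
  excluded_ids <- report$image_id[report$excluded]
  retained <- cohort
  retained$images <- cohort$images[setdiff(names(cohort$images), excluded_ids)]
  retained$labels <- dplyr::filter(cohort$labels, !.data$image_id %in% excluded_ids)
  list(cohort = retained,
       exclusions = dplyr::filter(report, .data$excluded),
       report = report)
}

#' Assign patients to five folds
#'
#' Patients are shuffled by the seed and dealt round-robin into `k` folds, so
#' patient counts per fold differ by at most one while image counts may
#' differ more (all of a patient's images inherit the patient's fold).
#'
#' @param patient_ids Character vector of unique patient ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Tibble (patient_id, fold) with fold in `0:(k-1)`; attribute
#'   `seed`.
#' @export
assign_folds <- function(patient_ids, k = 5L, seed = 1L) {
  patient_ids <- unique(as.character(patient_ids))
  if (length(patient_ids) < k) {
    abort(sprintf("Need at least %d patients for %d folds.", k, k),
          class = "lesioncam_configuration_error")
  }
  shuffled <- withr::with_seed(as.integer(seed), sample(patient_ids))
  out <- tibble::tibble(patient_id = shuffled,
                        fold = (seq_along(shuffled) - 1L) %% as.integer(k))
  out <- dplyr::arrange(out, .data$patient_id)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Rolling 3:1:1 cross-validation groups over five folds
#'
#' Group `g` trains on folds `(g, g+1, g+2) mod 5`, validates on
#' `(g+3) mod 5` and tests on `(g+4) mod 5`; each fold serves as the test set
#' exactly once. Only `k = 5` is supported, matching the fixed study design.
#'
#' @param k Number of folds; must be 5.
#' @return Tibble (group, train \[list of 3\], val, test).
#' @export
cross_validation_groups <- function(k = 5L) {
  if (k != 5L) {
    abort("Only the five-fold 3:1:1 rotation is supported.",
          class = "lesioncam_configuration_error")
  }
  g <- 0:4
  tibble::tibble(
    group = g,
    train = purrr::map(g, ~ (.x + 0:2) %% 5L),
    val = (g + 3L) %% 5L,
    test = (g + 4L) %% 5L
  )
}

#' Attach fold and train/val/test role to an image labels table
#'
#' @param labels Tibble with `image_id`, `patient_id`.
#' @param folds Output of [assign_folds()].
#' @param group Cross-validation group index in 0..4.
#' @return `labels` with `fold` and `role` (`"train"`, `"val"`, `"test"`)
#'   columns.
#' @export
cv_roles <- function(labels, folds, group = 0L) {
  grp <- dplyr::filter(cross_validation_groups(), .data$group == !!group)
  if (nrow(grp) != 1) {
    abort("`group` must be in 0..4.", class = "lesioncam_configuration_error")
  }
  out <- dplyr::left_join(labels, folds, by = "patient_id")
  train_folds <- grp$train[[1]]
  out$role <- dplyr::case_when(
    out$fold %in% train_folds ~ "train",
    out$fold == grp$val ~ "val",
    out$fold == grp$test ~ "test"
  )
  out
}

#' Sample a fixed-size per-class test set
#'
#' Draws exactly `n_per_class` images from each requested class of a test
#' fold, without replacement, so that test sets are comparable across
#' cross-validation groups despite unequal fold sizes.
#'
#' @param test_labels Tibble with `image_id` and `class`.
#' @param n_per_class Number of images to draw per class.
#' @param classes Classes to sample; defaults to all classes present.
#' @param seed Integer seed.
#' @return Subset tibble of `test_labels`.
#' @export
sample_fixed_test_set <- function(test_labels, n_per_class, classes = NULL,
                                  seed = 1L) {
  if (is.null(classes)) classes <- sort(unique(test_labels$class))
  withr::with_seed(as.integer(seed), {
    picks <- purrr::map(classes, function(cl) {
      ids <- test_labels$image_id[test_labels$class == cl]
      if (length(ids) < n_per_class) {
        abort(sprintf("Class '%s' has only %d test images; %d requested.",
                      cl, length(ids), n_per_class),
              class = "lesioncam_sampling_error")
      }
      sample(ids, n_per_class)
    })
    dplyr::filter(test_labels, .data$image_id %in% unlist(picks))
  })
}
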