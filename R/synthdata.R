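#' Lesion appearance parameters for the synthetic cohort generator
#'
#' Controls the geometry and appearance of planted lesions. The defaults give
#' a lesion that is visible to the eye but subtle: gastric-cancer depth cues on
#' endoscopy are textural and chromatic perturbations of the mucosa rather
#' than high-contrast objects, and submucosal invasion is additionally marked
#' by marginal elevation, which the generator renders as a bright rim.
#'
#' @param base_radius_fraction Mean lesion radius as a fraction of the image
#'   side; must lie in (0, 0.5).
#' @param boundary_irregularity Non-negative amplitude of the smooth radial
#'   perturbation of the lesion boundary. `0` yields an exact ellipse.
#' @param texture_contrast Amplitude in \[0, 1\] of the fine-grained texture
#'   roughness inside the lesion (the mucosal cue shared by both depth
#'   classes).
#' @param rim_strength Brightness in \[0, 1\] of the marginal rim rendered for
#'   submucosal (T1b) lesions, emulating marginal elevation.
#' @param color_shift Per-class hue offset applied inside the lesion;
#'   submucosal lesions receive a stronger shift.
#' @return A `lesion_params` list.
#' @export
#' @examples
#' lesion_params(base_radius_fraction = 0.2)
lesion_params <- function(base_radius_fraction = 0.14,
                          boundary_irregularity = 0.25,
                          texture_contrast = 0.25,
                          rim_strength = 0.35,
                          color_shift = 0.05) {
  if (!is.finite(base_radius_fraction) ||
      base_radius_fraction <= 0 || base_radius_fraction >= 0.5) {
    abort("`base_radius_fraction` must lie in (0, 0.5).",
          class = "lesioncam_parameter_error")
  }
  amps <- c(boundary_irregularity = boundary_irregularity,
            texture_contrast = texture_contrast,
            rim_strength = rim_strength,
            color_shift = color_shift)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    abort("All lesion amplitudes must be finite and non-negative.",
          class = "lesioncam_parameter_error")
  }
  if (texture_contrast > 1 || rim_strength > 1) {
    abort("`texture_contrast` and `rim_strength` must lie in [0, 1].",
          class = "lesioncam_parameter_error")
  }
  structure(list(base_radius_fraction = base_radius_fraction,
                 boundary_irregularity = boundary_irregularity,
                 texture_contrast = texture_contrast,
                 rim_strength = rim_strength,
                 color_shift = color_shift),
            class = "lesion_params")
}

#' Generate a random lesion mask
#'
#' Draws a single connected blob: an ellipse with a smoothed random radial
#' boundary perturbation, centred uniformly at random so that the blob fits in
#' frame. Masks whose foreground area falls outside 1--40% of the frame are
#' redrawn. Uses the current RNG state; seed with [set.seed()] or
#' [withr::with_seed()] for reproducibility.
#'
#' @param image_side Side length in pixels (>= 16).
#' @param params A [lesion_params()] object.
#' @param size_jitter Multiplicative jitter range for the lesion radius.
#' @return A logical `image_side` x `image_side` matrix with attribute
#'   `geometry` (centre, semi-axes, rotation).
#' @export
generate_lesion_mask <- function(image_side, params = lesion_params(),
                                 size_jitter = c(0.8, 1.25)) {
  if (!inherits(params, "lesion_params")) params <- do.call(lesion_params, params)
  if (image_side < 16) {
    abort("`image_side` must be at least 16 pixels.",
          class = "lesioncam_parameter_error")
  }
  side <- as.integer(image_side)
  lo_area <- 0.01 * side^2
  hi_area <- 0.40 * side^2
  irr <- min(params$boundary_irregularity, 0.8)
  for (attempt in seq_len(64L)) {
    r0 <- params$base_radius_fraction * side * runif(1, size_jitter[1], size_jitter[2])
    r0 <- min(r0, (side / 2 - 2) / (1 + irr))
    aspect <- runif(1, 0.6, 1)
    a <- r0
    b <- r0 * aspect
    phi <- runif(1, 0, pi)
    margin <- ceiling(a * (1 + irr)) + 1
    cx <- runif(1, margin, side - margin)
    cy <- runif(1, margin, side - margin)
    # smooth angular perturbation from low-order harmonics, bounded to [-1,1]
    nh <- 4L
    coef <- rnorm(2 * nh)
    jj <- matrix(rep(seq_len(side), each = side), side)   # column index (x)
    ii <- matrix(rep(seq_len(side), times = side), side)  # row index (y)
    dx <- jj - cx
    dy <- ii - cy
    u <- dx * cos(phi) + dy * sin(phi)
    v <- -dx * sin(phi) + dy * cos(phi)
    rho <- sqrt((u / a)^2 + (v / b)^2)
    if (irr > 0) {
      theta <- atan2(v, u)
      s <- matrix(0, side, side)
      for (h in seq_len(nh)) {
        s <- s + coef[h] * cos((h + 1) * theta) + coef[nh + h] * sin((h + 1) * theta)
      }
      smax <- max(abs(s))
      if (smax > 0) s <- s / smax
      boundary <- 1 + irr * s
    } else {
      boundary <- 1
    }
    mask <- rho <= boundary
    area <- sum(mask)
    if (area >= lo_area && area <= hi_area) {
      attr(mask, "geometry") <- list(centre = c(x = cx, y = cy),
                                     semi_axes = c(a = a, b = b),
                                     rotation = phi)
      return(mask)
    }
  }
  abort("Could not draw a lesion mask within the 1-40% area bounds.",
        class = "lesioncam_generation_error")
}

#' Render a synthetic endoscopy-like image
#'
#' The background is a warm-hued correlated-noise texture with vignetting and
#' a few bright specular glints. Inside the lesion mask, class-dependent
#' perturbations are applied: mucosal (T1a) lesions receive texture roughness
#' and a mild hue shift; submucosal (T1b) lesions receive the same plus a
#' marginal rim and a stronger hue shift. Non-lesion (nonEGC) frames carry no
#' mask and, with probability `benign_patch_prob`, a smooth benign darkening
#' that acts as a distractor. With all appearance amplitudes at zero the
#' lesion is invisible (mean intensity inside the mask matches outside).
#'
#' In addition, lesion-bearing frames carry (with probability 0.9, versus
#' 0.1 for clean frames) a global acquisition bias: a slightly dimmer,
#' more strongly vignetted rendering, as when a lesion is documented with a
#' closer view under different insufflation. This shortcut emulates a known
#' pathology of clinical collections — incidental frame-level cues that
#' co-occur with the diagnosis — which lets a classifier minimize
#' cross-entropy while attending to non-lesion regions; it is what makes
#' localization supervision consequential. Set `shortcut_artifact = FALSE`
#' for bias-free rendering.
#'
#' @param class_label One of `"nonEGC"`, `"T1a"`, `"T1b"`.
#' @param mask Logical lesion mask; required for lesion classes, forbidden for
#'   `"nonEGC"`.
#' @param params A [lesion_params()] object.
#' @param image_side Side in pixels; defaults to the mask's side, else 128.
#' @param benign_patch_prob Probability of a benign distractor patch on
#'   nonEGC frames.
#' @param shortcut_artifact Render the class-correlated acquisition bias.
#' @param vignetting Apply radial darkening toward the frame border.
#' @return A `labeled_image`: list with `pixels` (H x W x 3 array in \[0,1\]),
#'   `class_label`, `lesion_mask` (or `NULL`), `quality_flags`.
#' @export
render_image <- function(class_label, mask = NULL, params = lesion_params(),
                         image_side = NULL, benign_patch_prob = 0.3,
                         shortcut_artifact = TRUE, vignetting = TRUE) {
  class_label <- match.arg(class_label, c("nonEGC", "T1a", "T1b"))
  if ((class_label == "nonEGC") != is.null(mask)) {
    abort("A lesion mask must be supplied iff the class is a lesion class.",
          class = "lesioncam_consistency_error")
  }
  if (is.null(image_side)) image_side <- if (!is.null(mask)) nrow(mask) else 128L
  side <- as.integer(image_side)
  if (!is.null(mask)) {
    mask <- as_logical_mask(mask)
    stopifnot(nrow(mask) == side, ncol(mask) == side, sum(mask) >= 1)
  }

  base <- c(0.72, 0.46, 0.38) + rnorm(3, 0, 0.02)
  lum_noise <- 0.06 * smooth_noise(side, sigma = 3)
  jj <- matrix(rep(seq_len(side), each = side), side)
  ii <- matrix(rep(seq_len(side), times = side), side)
  r2 <- ((ii - (side + 1) / 2)^2 + (jj - (side + 1) / 2)^2) / (side / 2)^2
  vignette <- if (isTRUE(vignetting)) 1 - 0.22 * r2 else 1

  px <- array(0, dim = c(side, side, 3))
  for (ch in 1:3) {
    px[, , ch] <- base[ch] * vignette + lum_noise +
      0.02 * smooth_noise(side, sigma = 1.5)
  }

  # specular glints: small bright spots, class-independent distractors
  n_glint <- sample(1:3, 1)
  for (g in seq_len(n_glint)) {
    gx <- runif(1, 0.1 * side, 0.9 * side)
    gy <- runif(1, 0.1 * side, 0.9 * side)
    gs <- runif(1, 1, 2.5)
    spot <- 0.25 * exp(-(((ii - gy)^2 + (jj - gx)^2) / (2 * gs^2)))
    for (ch in 1:3) px[, , ch] <- px[, , ch] + spot
  }

  if (class_label == "nonEGC") {
    if (runif(1) < benign_patch_prob) {
      bx <- runif(1, 0.25 * side, 0.75 * side)
      by <- runif(1, 0.25 * side, 0.75 * side)
      bs <- runif(1, 0.08, 0.15) * side
      patch <- exp(-(((ii - by)^2 + (jj - bx)^2) / (2 * bs^2)))
      for (ch in 1:3) px[, , ch] <- px[, , ch] - 0.08 * patch
    }
  } else {
    rough <- params$texture_contrast * 0.35 * smooth_noise(side, sigma = 0.8)
    shift <- params$color_shift * if (class_label == "T1b") 1.6 else 1
    dch <- c(shift, -0.3 * shift, -shift)
    for (ch in 1:3) {
      px[, , ch] <- px[, , ch] + mask * (rough + dch[ch])
    }
    if (class_label == "T1b" && params$rim_strength > 0) {
      band <- (dilate1(mask) & !erode1(mask))
      add <- params$rim_strength * 0.4 * band
      for (ch in 1:3) px[, , ch] <- px[, , ch] + add
    }
  }

  if (isTRUE(shortcut_artifact)) {
    p_bias <- if (class_label == "nonEGC") 0.05 else 0.95
    if (runif(1) < p_bias) {
      dim_factor <- runif(1, 0.85, 0.92)
      extra_vignette <- 1 - 0.15 * r2
      for (ch in 1:3) px[, , ch] <- px[, , ch] * dim_factor * extra_vignette
    }
  }

  px <- clamp01(px)
  structure(list(image_id = NA_character_, patient_id = NA_character_,
                 pixels = px, class_label = class_label,
                 lesion_mask = mask, quality_flags = character(0)),
            class = "labeled_image")
}

#' Generate a seeded synthetic patient cohort
#'
#' Emulates the statistical structure of a patient-grouped endoscopic image
#' collection: each patient contributes several images of a single class,
#' classes are heavily imbalanced in favour of non-lesion frames, all images
#' of a patient share lesion morphology up to viewpoint/scale jitter, and
#' lesion classes carry pixel-aligned binary masks. Content is a pure
#' function of `(seed, parameters)`.
#'
#' @param n_patients Number of patients (>= 5 so all five folds are
#'   populated).
#' @param class_mix Probabilities for `(nonEGC, T1a, T1b)`; must sum to 1.
#'   The default mirrors the heavy imbalance of clinical collections, where
#'   most frames show non-neoplastic mucosa.
#' @param images_per_patient Integer range `c(min, max)` of images per
#'   patient.
#' @param image_side Image side in pixels.
#' @param params A [lesion_params()] object.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param shortcut_artifact Render the class-correlated particle speck (see
#'   [render_image()]).
#' @return A `lesion_cohort`: list with `images` (named list of
#'   `labeled_image`), `labels` (tibble: image_id, patient_id, class),
#'   `seed`, `params`.
#' @export
#' @examples
#' co <- generate_cohort(8, image_side = 32, seed = 1)
#' co$labels
generate_cohort <- function(n_patients,
                            class_mix = c(nonEGC = 0.852, T1a = 0.078, T1b = 0.070),
                            images_per_patient = c(2L, 6L),
                            image_side = 128L,
                            params = lesion_params(),
                            seed = 1L,
                            shortcut_artifact = TRUE) {
  if (n_patients < 5) {
    abort("`n_patients` must be at least 5 so that five folds are populated.",
          class = "lesioncam_parameter_error")
  }
  if (length(class_mix) != 3 || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-8) {
    abort("`class_mix` must be 3 non-negative probabilities summing to 1.",
          class = "lesioncam_parameter_error")
  }
  classes <- c("nonEGC", "T1a", "T1b")
  lo <- as.integer(images_per_patient[1])
  hi <- as.integer(images_per_patient[2])
  stopifnot(lo >= 1, hi >= lo)

  withr::with_seed(as.integer(seed), {
    images <- list()
    rows <- vector("list", n_patients)
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%04d", p)
      cls <- sample(classes, 1, prob = class_mix)
      n_img <- if (hi > lo) sample(lo:hi, 1) else lo
      # patient-level morphology: shared size/irregularity, jittered per image
      p_params <- params
      p_params$base_radius_fraction <-
        min(0.45, params$base_radius_fraction * runif(1, 0.85, 1.2))
      ids <- character(n_img)
      for (k in seq_len(n_img)) {
        iid <- sprintf("%s_I%02d", pid, k)
        msk <- if (cls != "nonEGC") {
          generate_lesion_mask(image_side, p_params, size_jitter = c(0.9, 1.1))
        } else NULL
        img <- render_image(cls, mask = msk, params = p_params,
                            image_side = image_side,
                            shortcut_artifact = shortcut_artifact)
        img$image_id <- iid
        img$patient_id <- pid
        images[[iid]] <- img
        ids[k] <- iid
      }
      rows[[p]] <- tibble::tibble(image_id = ids, patient_id = pid, class = cls)
    }
    labels <- dplyr::bind_rows(rows)
    structure(list(images = images, labels = labels, seed = as.integer(seed),
                   class_mix = class_mix,
                   images_per_patient = c(lo, hi),
                   image_side = as.integer(image_side), params = params),
              class = "lesion_cohort")
  })
}

#' @export
print.lesion_cohort <- function(x, ...) {
  counts <- table(x$labels$class)
  cat("<lesion_cohort> ", nrow(x$labels), " images, ",
      length(unique(x$labels$patient_id)), " patients, side ",
      x$image_side, " px, seed ", x$seed, "\n", sep = "")
  print(counts)
  invisible(x)
}

#' Write a cohort to disk as PNG images plus a labels table
#'
#' Images are written as 8-bit RGB PNG, masks as 8-bit grayscale PNG with
#' foreground 255, the labels table as CSV (image_id, patient_id, class,
#' mask_path), and a JSON sidecar records the seed and generation parameters.
#'
#' @param cohort A `lesion_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path to the labels CSV.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  mask_paths <- character(nrow(cohort$labels))
  for (i in seq_len(nrow(cohort$labels))) {
    iid <- cohort$labels$image_id[i]
    img <- cohort$images[[iid]]
    png::writePNG(img$pixels, file.path(dir, "images", paste0(iid, ".png")))
    if (!is.null(img$lesion_mask)) {
      mp <- file.path("masks", paste0(iid, ".png"))
      png::writePNG(matrix(as.numeric(img$lesion_mask), nrow(img$lesion_mask)),
                    file.path(dir, mp))
      mask_paths[i] <- mp
    } else {
      mask_paths[i] <- ""
    }
  }
  labels <- dplyr::mutate(cohort$labels, mask_path = mask_paths)
  labels_path <- file.path(dir, "labels.csv")
  utils::write.csv(labels, labels_path, row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$seed, image_side = cohort$image_side,
         class_mix = as.list(cohort$class_mix),
         images_per_patient = cohort$images_per_patient,
         params = unclass(cohort$params)),
    file.path(dir, "generation.json"), auto_unbox = TRUE, digits = NA)
  invisible(labels_path)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir Directory containing `labels.csv`, `images/` and `masks/`.
#' @return A `lesion_cohort`.
#' @export
read_cohort <- function(dir) {
  labels <- tibble::as_tibble(utils::read.csv(file.path(dir, "labels.csv"),
                                              stringsAsFactors = FALSE))
  meta <- jsonlite::read_json(file.path(dir, "generation.json"),
                              simplifyVector = TRUE)
  images <- list()
  for (i in seq_len(nrow(labels))) {
    iid <- labels$image_id[i]
    px <- png::readPNG(file.path(dir, "images", paste0(iid, ".png")))
    msk <- NULL
    mp <- labels$mask_path[i]
    if (!is.na(mp) && nzchar(mp)) {
      m <- png::readPNG(file.path(dir, labels$mask_path[i]))
      if (length(dim(m)) == 3) m <- m[, , 1]
      msk <- m >= 0.5
    }
    images[[iid]] <- structure(
      list(image_id = iid, patient_id = labels$patient_id[i], pixels = px,
           class_label = labels$class[i], lesion_mask = msk,
           quality_flags = character(0)),
      class = "labeled_image")
  }
  structure(list(images = images,
                 labels = dplyr::select(labels, "image_id", "patient_id", "class"),
                 seed = meta$seed, class_mix = unlist(meta$class_mix),
                 images_per_patient = meta$images_per_patient,
                 image_side = meta$image_side,
                 params = do.call(lesion_params, as.list(meta$params))),
            class = "lesion_cohort")
}
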