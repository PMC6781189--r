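#' Compute a Grad-CAM activation map
#'
#' Gradient-weighted class activation mapping at the last convolutional
#' layer: the channel weights are the spatial averages of the gradient of the
#' target class score with respect to each feature map,
#' `alpha_k = mean_ij( d y_c / d A_k[i,j] )`, and the map is the rectified
#' channel-weighted sum `L_c = max(0, sum_k alpha_k A_k)`. Computed in a
#' single forward plus head-backward pass.
#'
#' @param model A `cam_cnn` model.
#' @param image Image array or `labeled_image` matching the model input side.
#' @param class_index Target class index `c` in `1..n_classes`, or a class
#'   name.
#' @return A `cam_map`: list with `values` (u x v non-negative matrix),
#'   `channel_weights` (the K pooled-gradient weights), `target_class`,
#'   `normalized = FALSE`.
#' @export
compute_cam <- function(model, image, class_index) {
  if (is.character(class_index)) {
    class_index <- match(class_index, model$classes)
  }
  if (is.na(class_index) || class_index < 1 || class_index > model$n_classes) {
    abort("`class_index` is not a valid class.", class = "lesioncam_input_error")
  }
  x <- if (inherits(image, "labeled_image")) image$pixels else image
  fw <- forward_features(model, x)
  onehot <- rep(0, model$n_classes)
  onehot[class_index] <- 1
  hb <- head_backward(model, fw$A, onehot)   # dA = d y_c / d A
  K <- dim(fw$A)[3]
  alpha <- vapply(seq_len(K), function(k) mean(hb$dA[, , k]), numeric(1))
  uv <- dim(fw$A)[1:2]
  Amat <- matrix(fw$A, prod(uv), K)
  S <- matrix(Amat %*% alpha, uv[1], uv[2])
  new_cam(pmax(S, 0), channel_weights = alpha,
          target_class = as.integer(class_index))
}

new_cam <- function(values, channel_weights = NULL, target_class = NA_integer_,
                    normalized = FALSE) {
  structure(list(values = values, channel_weights = channel_weights,
                 target_class = target_class, normalized = normalized),
            class = "cam_map")
}

#' @export
print.cam_map <- function(x, ...) {
  cat("<cam_map> ", nrow(x$values), "x", ncol(x$values),
      if (x$normalized) ", normalized" else "",
      ", max ", signif(max(x$values), 4), "\n", sep = "")
  invisible(x)
}

#' Normalize a CAM to \[0, 1\]
#'
#' Divides by the maximum when it is positive; an all-zero map is returned
#' unchanged (and flagged normalized). Idempotent.
#'
#' @param cam A `cam_map` or a non-negative matrix.
#' @return A normalized `cam_map`.
#' @export
normalize_cam <- function(cam) {
  if (is.matrix(cam)) cam <- new_cam(cam)
  if (any(cam$values < 0)) {
    abort("CAM values must be non-negative.",
          class = "lesioncam_invariant_error")
  }
  mx <- max(cam$values)
  if (mx > 0) cam$values <- cam$values / mx
  cam$normalized <- TRUE
  cam
}

#' Upsample a CAM by bilinear interpolation
#'
#' Pixel-centre aligned bilinear interpolation to a larger grid (typically
#' image resolution, for localization scoring). Non-negativity is preserved;
#' downsizing is refused.
#'
#' @param cam A `cam_map` or matrix.
#' @param target Integer target size `c(H, W)` (a single value is square).
#' @return A `cam_map` of the target size.
#' @export
upsample_cam <- function(cam, target) {
  m <- if (inherits(cam, "cam_map")) cam$values else cam
  if (length(target) == 1) target <- c(target, target)
  H <- as.integer(target[1]); W <- as.integer(target[2])
  if (H < nrow(m) || W < ncol(m)) {
    abort("`upsample_cam()` cannot reduce the map size.",
          class = "lesioncam_parameter_error")
  }
  out <- bilinear_resize(m, H, W)
  if (inherits(cam, "cam_map")) {
    res <- cam
    res$values <- out
    res
  } else {
    new_cam(out)
  }
}

# Pixel-centre aligned bilinear interpolation of a matrix to H x W.
bilinear_resize <- function(m, H, W) {
  src_coord <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pmin(pmax(s, 1), n_in)
  }
  si <- src_coord(H, nrow(m))
  sj <- src_coord(W, ncol(m))
  i0 <- pmin(floor(si), nrow(m) - ifelse(nrow(m) > 1, 1, 0))
  j0 <- pmin(floor(sj), ncol(m) - ifelse(ncol(m) > 1, 1, 0))
  i1 <- pmin(i0 + 1, nrow(m))
  j1 <- pmin(j0 + 1, ncol(m))
  fi <- si - i0
  fj <- sj - j0
  m00 <- m[i0, j0, drop = FALSE]
  m10 <- m[i1, j0, drop = FALSE]
  m01 <- m[i0, j1, drop = FALSE]
  m11 <- m[i1, j1, drop = FALSE]
  wi <- matrix(fi, H, W)
  wj <- matrix(fj, H, W, byrow = TRUE)
  m00 * (1 - wi) * (1 - wj) + m10 * wi * (1 - wj) +
    m01 * (1 - wi) * wj + m11 * wi * wj
}

#' Downsample a binary mask to the CAM grid
#'
#' Area-mean pooling onto the target grid followed by thresholding at 0.5,
#' the representation used for the localization loss at feature resolution.
#'
#' @param mask Logical or 0/1 matrix at image resolution.
#' @param target Integer `c(u, v)` target size (single value is square).
#' @return A `u x v` numeric 0/1 matrix.
#' @export
downsample_mask <- function(mask, target) {
  if (length(target) == 1) target <- c(target, target)
  u <- as.integer(target[1]); v <- as.integer(target[2])
  mask <- as_logical_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  bi <- pmin(floor((seq_len(H) - 0.5) * u / H) + 1L, u)
  bj <- pmin(floor((seq_len(W) - 0.5) * v / W) + 1L, v)
  agg <- t(rowsum(t(rowsum(mask + 0, bi)), bj))
  cnt <- t(rowsum(t(rowsum(matrix(1, H, W), bi)), bj))
  out <- (agg / cnt >= 0.5) + 0
  dimnames(out) <- NULL
  out
}
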