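#' Build a convolutional classifier
#'
#' Constructs a compact convolutional network whose class scores, last
#' convolutional feature maps, and the gradients of any class score with
#' respect to those feature maps are all accessible — the contract required
#' for Grad-CAM computation and for attention-supervised training. Three
#' architectures are provided:
#'
#' * `"vgg-style"` — three 3x3 conv stages (8, 16, 32 channels) with max
#'   pooling after the first two; overall downsampling factor 4.
#' * `"resnet-style"` — a conv stem followed by two residual blocks with max
#'   pooling between stages; downsampling factor 4.
#' * `"tiny-test"` — two conv stages (8, 16 channels) with one pooling;
#'   downsampling factor 2. Intended for desk-scale tests and oracles.
#'
#' The classifier head is global average pooling over the last conv maps
#' followed by a dense layer. Weights are He-initialized from the seed.
#'
#' @param architecture One of `"vgg-style"`, `"resnet-style"`, `"tiny-test"`.
#' @param n_classes 2 or 3.
#' @param input_side Input image side in pixels; must be a multiple of the
#'   architecture's downsampling factor.
#' @param classes Optional character names for the classes (length
#'   `n_classes`); defaults to `"class1"`, ... .
#' @param seed Integer seed for weight initialization.
#' @param pretrained If `TRUE`, request pretrained weights. No pretrained
#'   weights are bundled with the package, so this raises a configuration
#'   error; random seeded initialization is the supported path.
#' @return A `cam_cnn` model object.
#' @export
#' @examples
#' m <- build_model("tiny-test", n_classes = 2, input_side = 16, seed = 1)
#' m
build_model <- function(architecture = c("vgg-style", "resnet-style", "tiny-test"),
                        n_classes = 2L, input_side = 64L, classes = NULL,
                        seed = 1L, pretrained = FALSE) {
  architecture <- match.arg(architecture)
  if (!n_classes %in% c(2L, 3L)) {
    abort("`n_classes` must be 2 or 3.", class = "lesioncam_configuration_error")
  }
  if (isTRUE(pretrained)) {
    abort("No pretrained weights are bundled; use seeded random initialization.",
          class = "lesioncam_configuration_error")
  }
  spec <- switch(architecture,
    "tiny-test" = list(downsample = 2L,
                       layers = list(
                         list(type = "conv", cin = 3L, cout = 8L),
                         list(type = "relu"),
                         list(type = "pool"),
                         list(type = "conv", cin = 8L, cout = 16L),
                         list(type = "relu"))),
    "vgg-style" = list(downsample = 4L,
                       layers = list(
                         list(type = "conv", cin = 3L, cout = 8L),
                         list(type = "relu"),
                         list(type = "pool"),
                         list(type = "conv", cin = 8L, cout = 16L),
                         list(type = "relu"),
                         list(type = "pool"),
                         list(type = "conv", cin = 16L, cout = 32L),
                         list(type = "relu"))),
    "resnet-style" = list(downsample = 4L,
                          layers = list(
                            list(type = "conv", cin = 3L, cout = 16L),
                            list(type = "relu"),
                            list(type = "pool"),
                            list(type = "resblock", channels = 16L),
                            list(type = "pool"),
                            list(type = "resblock", channels = 16L)))
  )
  if (input_side %% spec$downsample != 0) {
    abort(sprintf("`input_side` must be a multiple of %d for '%s'.",
                  spec$downsample, architecture),
          class = "lesioncam_configuration_error")
  }
  k_last <- 0L
  for (ly in spec$layers) {
    if (ly$type == "conv") k_last <- ly$cout
    if (ly$type == "resblock") k_last <- ly$channels
  }

  layers <- withr::with_seed(as.integer(seed), {
    lapply(spec$layers, function(ly) {
      if (ly$type == "conv") {
        sd <- sqrt(2 / (9 * ly$cin))
        ly$W <- matrix(rnorm(9 * ly$cin * ly$cout, 0, sd), 9 * ly$cin, ly$cout)
        ly$b <- rep(0, ly$cout)
      } else if (ly$type == "resblock") {
        sd <- sqrt(2 / (9 * ly$channels))
        ly$W1 <- matrix(rnorm(9 * ly$channels^2, 0, sd), 9 * ly$channels, ly$channels)
        ly$b1 <- rep(0, ly$channels)
        ly$W2 <- matrix(rnorm(9 * ly$channels^2, 0, sd), 9 * ly$channels, ly$channels)
        ly$b2 <- rep(0, ly$channels)
      }
      ly
    })
  })
  head <- withr::with_seed(as.integer(seed) + 1L, {
    list(W = matrix(rnorm(k_last * n_classes, 0, 1 / sqrt(k_last)),
                    k_last, n_classes),
         b = rep(0, n_classes))
  })
  if (is.null(classes)) classes <- paste0("class", seq_len(n_classes))
  stopifnot(length(classes) == n_classes)
  structure(list(architecture = architecture, n_classes = as.integer(n_classes),
                 input_side = as.integer(input_side),
                 downsample = spec$downsample, k_last = k_last,
                 layers = layers, head = head, classes = classes,
                 seed = as.integer(seed)),
            class = "cam_cnn")
}

#' @export
print.cam_cnn <- function(x, ...) {
  uv <- x$input_side %/% x$downsample
  cat("<cam_cnn> ", x$architecture, ", ", x$n_classes, " classes (",
      paste(x$classes, collapse = ", "), "), input ", x$input_side,
      " px, last-conv maps ", x$k_last, " x ", uv, "x", uv, "\n", sep = "")
  invisible(x)
}

relu_fwd <- function(a) {
  a[a < 0] <- 0
  a
}

# Forward pass up to the last convolutional feature maps A (K maps of u x v).
# Returns list(A, cache) where cache holds per-layer intermediates for
# backward().
forward_features <- function(model, x) {
  if (is.null(dim(x)) || length(dim(x)) != 3) {
    abort("Input must be an H x W x C array.", class = "lesioncam_input_error")
  }
  if (dim(x)[1] != model$input_side || dim(x)[2] != model$input_side) {
    abort("Input side does not match the model.", class = "lesioncam_input_error")
  }
  a <- x
  cache <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$type == "conv") {
      cache[[li]] <- list(input = a)
      a <- .conv3_forward(a, ly$W, ly$b)
    } else if (ly$type == "relu") {
      m <- a > 0
      cache[[li]] <- list(mask = m)
      a <- a * m
    } else if (ly$type == "pool") {
      r <- .maxpool2_forward(a)
      cache[[li]] <- list(argmax = r$argmax, H = dim(a)[1], W = dim(a)[2])
      a <- r$out
    } else if (ly$type == "resblock") {
      x0 <- a
      h1 <- .conv3_forward(x0, ly$W1, ly$b1)
      m1 <- h1 > 0
      h1r <- h1 * m1
      h2 <- .conv3_forward(h1r, ly$W2, ly$b2)
      s <- h2 + x0
      m2 <- s > 0
      cache[[li]] <- list(x0 = x0, h1r = h1r, m1 = m1, m2 = m2)
      a <- s * m2
    }
  }
  list(A = a, cache = cache)
}

# Class scores from the last-conv feature maps: global average pooling
# followed by the dense head.
head_forward <- function(model, A) {
  g <- apply(A, 3, mean)
  drop(crossprod(model$head$W, g)) + model$head$b
}

# Gradient of the score vector contraction `sum(dscores * y)` with respect to
# A, plus the head parameter gradients.
head_backward <- function(model, A, dscores) {
  g <- apply(A, 3, mean)
  uv <- prod(dim(A)[1:2])
  dg <- drop(model$head$W %*% dscores)
  dA <- array(rep(dg / uv, each = uv), dim = dim(A))
  list(dA = dA, dW = outer(g, dscores), db = dscores)
}

# Backward pass from a gradient at the feature maps down through the layers.
# Returns per-layer parameter gradients (same shapes as the weights).
backward_features <- function(model, cache, dA) {
  grads <- vector("list", length(model$layers))
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    cc <- cache[[li]]
    if (ly$type == "conv") {
      bw <- .conv3_backward(cc$input, ly$W, dA)
      grads[[li]] <- list(W = bw$dW, b = as.vector(bw$db))
      dA <- bw$dx
    } else if (ly$type == "relu") {
      dA <- dA * cc$mask
    } else if (ly$type == "pool") {
      dA <- .maxpool2_backward(dA, cc$argmax, cc$H, cc$W)
    } else if (ly$type == "resblock") {
      ds <- dA * cc$m2
      bw2 <- .conv3_backward(cc$h1r, ly$W2, ds)
      dh1 <- bw2$dx * cc$m1
      bw1 <- .conv3_backward(cc$x0, ly$W1, dh1)
      grads[[li]] <- list(W1 = bw1$dW, b1 = as.vector(bw1$db),
                          W2 = bw2$dW, b2 = as.vector(bw2$db))
      dA <- bw1$dx + ds
    }
  }
  grads
}

model_scores <- function(model, image) {
  x <- if (inherits(image, "labeled_image")) image$pixels else image
  head_forward(model, forward_features(model, x)$A)
}

#' Predict class probabilities
#'
#' Inference is deterministic (no stochastic layers). Batch order is
#' preserved.
#'
#' @param object A `cam_cnn` model.
#' @param images A single image array, a `labeled_image`, or a list of
#'   either.
#' @param type `"prob"` for softmax probabilities, `"score"` for raw class
#'   scores, `"class"` for the argmax label.
#' @param ... Unused.
#' @return A tibble with one row per image: `image_id` plus one `.pred_*`
#'   column per class (or a `.pred_class` column).
#' @export
predict.cam_cnn <- function(object, images, type = c("prob", "score", "class"),
                            ...) {
  type <- match.arg(type)
  if (inherits(images, "labeled_image") ||
      (is.array(images) && length(dim(images)) == 3)) {
    images <- list(images)
  }
  ids <- purrr::map_chr(images, function(im) {
    if (inherits(im, "labeled_image") && !is.na(im$image_id)) im$image_id
    else NA_character_
  })
  scores <- t(vapply(images, function(im) model_scores(object, im),
                     numeric(object$n_classes)))
  out <- tibble::tibble(image_id = ids)
  if (type == "score") {
    colnames(scores) <- paste0(".score_", object$classes)
    return(dplyr::bind_cols(out, tibble::as_tibble(scores)))
  }
  probs <- t(apply(scores, 1, softmax))
  if (type == "class") {
    out$.pred_class <- object$classes[max.col(probs, ties.method = "first")]
    return(out)
  }
  colnames(probs) <- paste0(".pred_", object$classes)
  dplyr::bind_cols(out, tibble::as_tibble(probs))
}

# Flat parameter list (for the optimizer) and its inverse.
get_params <- function(model) {
  ps <- list()
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$type == "conv") {
      ps[[paste0("L", li, ".W")]] <- ly$W
      ps[[paste0("L", li, ".b")]] <- ly$b
    } else if (ly$type == "resblock") {
      ps[[paste0("L", li, ".W1")]] <- ly$W1
      ps[[paste0("L", li, ".b1")]] <- ly$b1
      ps[[paste0("L", li, ".W2")]] <- ly$W2
      ps[[paste0("L", li, ".b2")]] <- ly$b2
    }
  }
  ps[["head.W"]] <- model$head$W
  ps[["head.b"]] <- model$head$b
  ps
}

set_params <- function(model, ps) {
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$type == "conv") {
      model$layers[[li]]$W <- ps[[paste0("L", li, ".W")]]
      model$layers[[li]]$b <- ps[[paste0("L", li, ".b")]]
    } else if (ly$type == "resblock") {
      model$layers[[li]]$W1 <- ps[[paste0("L", li, ".W1")]]
      model$layers[[li]]$b1 <- ps[[paste0("L", li, ".b1")]]
      model$layers[[li]]$W2 <- ps[[paste0("L", li, ".W2")]]
      model$layers[[li]]$b2 <- ps[[paste0("L", li, ".b2")]]
    }
  }
  model$head$W <- ps[["head.W"]]
  model$head$b <- ps[["head.b"]]
  model
}

# Gradients in get_params() layout from backward_features() + head grads.
collect_grads <- function(model, layer_grads, head_grad) {
  gs <- list()
  for (li in seq_along(model$layers)) {
    lg <- layer_grads[[li]]
    if (is.null(lg)) next
    for (nm in names(lg)) gs[[paste0("L", li, ".", nm)]] <- lg[[nm]]
  }
  gs[["head.W"]] <- head_grad$dW
  gs[["head.b"]] <- head_grad$db
  gs
}
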