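#' Training configuration
#'
#' @param loss_mode `"plain"` (cross-entropy only) or `"lesion"` (weighted
#'   sum of cross-entropy and the Grad-CAM localization loss).
#' @param w_ce,w_cam Non-negative weights of the classification and
#'   localization terms. `w_cam` is ignored in plain mode; `w_ce + w_cam`
#'   must be positive. The localization term is a cell-averaged squared
#'   error, whose per-parameter gradients are roughly an order of magnitude
#'   smaller than the cross-entropy's, so the default `w_cam = 10` puts the
#'   two terms on comparable gradient scales.
#' @param learning_rate Adam learning rate.
#' @param epochs Number of training epochs.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed controlling shuffling (and nothing else — the
#'   model carries its own initialization seed).
#' @param cam_loss Functional form of the localization term: `"mse"` (mean
#'   squared difference between the normalized CAM and the binary mask) or
#'   `"dice"` (soft-Dice discrepancy).
#' @param balance_classes Draw each epoch's training indices with
#'   class-balancing weights (inverse class frequency, with replacement), so
#'   minority lesion classes are seen as often as the majority class.
#'   Without this, heavily imbalanced cohorts keep the optimizer in the
#'   majority-class regime for many epochs.
#' @param pretrained Passed through to model builders that support it.
#' @return A `training_config` list.
#' @export
training_config <- function(loss_mode = c("plain", "lesion"),
                            w_ce = 1, w_cam = 10,
                            learning_rate = 1e-3, epochs = 10L,
                            batch_size = 16L, seed = 1L,
                            cam_loss = c("mse", "dice"),
                            balance_classes = TRUE,
                            pretrained = FALSE) {
  loss_mode <- match.arg(loss_mode)
  cam_loss <- match.arg(cam_loss)
  if (w_ce < 0 || w_cam < 0) {
    abort("Loss weights must be non-negative.",
          class = "lesioncam_configuration_error")
  }
  if (w_ce + w_cam <= 0) {
    abort("`w_ce + w_cam` must be positive.",
          class = "lesioncam_configuration_error")
  }
  structure(list(loss_mode = loss_mode, w_ce = w_ce, w_cam = w_cam,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 cam_loss = cam_loss,
                 balance_classes = isTRUE(balance_classes),
                 pretrained = isTRUE(pretrained)),
            class = "training_config")
}

#' Cross-entropy classification loss
#'
#' `-log p(true class)`, with the probability clamped at `1e-12`.
#'
#' @param probs Probability vector (one image) or matrix (rows = images).
#' @param true_label Integer class index (or vector of them).
#' @return Scalar (or vector) loss.
#' @export
cross_entropy <- function(probs, true_label) {
  if (is.matrix(probs)) {
    stopifnot(length(true_label) == nrow(probs))
    if (any(true_label < 1 | true_label > ncol(probs))) {
      abort("Invalid label index.", class = "lesioncam_input_error")
    }
    p <- probs[cbind(seq_len(nrow(probs)), true_label)]
  } else {
    if (true_label < 1 || true_label > length(probs)) {
      abort("Invalid label index.", class = "lesioncam_input_error")
    }
    p <- probs[true_label]
  }
  -log(pmax(p, 1e-12))
}

#' Grad-CAM localization loss
#'
#' Discrepancy between a normalized CAM and a binary lesion mask on the same
#' grid. For images without a lesion the mask is all-zero, so any activation
#' is penalized. `"mse"` is the mean squared cell-wise difference; `"dice"`
#' is `1 - 2|C.M| / (|C|^2 + |M|^2)` on the soft map.
#'
#' @param cam A normalized `cam_map` or a matrix with values in \[0,1\].
#' @param mask Binary matrix of the same shape, or `NULL` (treated as
#'   all-zero).
#' @param method `"mse"` or `"dice"`.
#' @return Scalar loss.
#' @export
cam_localization_loss <- function(cam, mask = NULL, method = c("mse", "dice")) {
  method <- match.arg(method)
  m <- if (inherits(cam, "cam_map")) {
    if (!cam$normalized) {
      abort("CAM must be normalized before the localization loss.",
            class = "lesioncam_input_error")
    }
    cam$values
  } else cam
  if (max(m) > 1 + 1e-9 || min(m) < 0) {
    abort("CAM values must lie in [0, 1].", class = "lesioncam_input_error")
  }
  if (is.null(mask)) mask <- matrix(0, nrow(m), ncol(m))
  mask <- mask + 0
  if (!all(dim(mask) == dim(m))) {
    abort("CAM and mask shapes differ.", class = "lesioncam_input_error")
  }
  if (method == "mse") {
    mean((m - mask)^2)
  } else {
    1 - 2 * sum(m * mask) / (sum(m^2) + sum(mask^2) + 1e-8)
  }
}

#' Combine classification and localization terms
#'
#' @param ce_term Cross-entropy term.
#' @param cam_term Localization term (ignored in plain mode).
#' @param config A [training_config()].
#' @return A `loss_value` list: `total`, `ce_term`, `cam_term`, satisfying
#'   `total = w_ce * ce_term + w_cam * cam_term` (with the cam contribution
#'   identically zero in plain mode).
#' @export
composite_loss <- function(ce_term, cam_term, config) {
  if (config$loss_mode == "plain") {
    out <- list(total = ce_term, ce_term = ce_term, cam_term = 0)
  } else {
    out <- list(total = config$w_ce * ce_term + config$w_cam * cam_term,
                ce_term = ce_term, cam_term = cam_term)
  }
  structure(out, class = "loss_value")
}

# Forward + loss + full gradient for a single image. In lesion mode the CAM
# for the TRUE class is computed from the current head weights; its pooled
# gradients (alpha) and the normalization maximum are treated as constants
# when backpropagating the localization term (first-order attention
# supervision), so the term's gradient flows through the feature maps only.
image_step <- function(model, x, yidx, mask, config) {
  fw <- forward_features(model, x)
  A <- fw$A
  scores <- head_forward(model, A)
  p <- softmax(scores)
  ce <- -log(max(p[yidx], 1e-12))
  dscores <- p
  dscores[yidx] <- dscores[yidx] - 1

  cam_term <- 0
  dA_cam <- NULL
  if (config$loss_mode == "lesion") {
    dims <- dim(A)
    uv <- dims[1:2]
    K <- dims[3]
    alpha <- model$head$W[, yidx] / prod(uv)
    S <- matrix(matrix(A, prod(uv), K) %*% alpha, uv[1], uv[2])
    cam <- pmax(S, 0)
    mx <- max(cam)
    # Stop-gradient normalization scale, floored so that a nearly dead map
    # does not produce exploding 1/max gradients.
    scale <- max(mx, 0.05)
    msk <- if (!is.null(mask)) downsample_mask(mask, uv) else
      matrix(0, uv[1], uv[2])
    camn <- cam / scale
    if (config$cam_loss == "mse") {
      cam_term <- mean((camn - msk)^2)
      dcamn <- 2 * (camn - msk) / prod(uv)
    } else {
      num <- 2 * sum(camn * msk)
      den <- sum(camn^2) + sum(msk^2) + 1e-8
      cam_term <- 1 - num / den
      dcamn <- -(2 * msk * den - num * 2 * camn) / den^2
    }
    # Rectifier subgradient: active where the map is positive, and also at
    # mask-positive cells so an all-dead map can be resurrected by the
    # localization term (otherwise a collapsed CAM has zero gradient and the
    # attention supervision can never recover it).
    active <- (S > 0) | (msk > 0)
    dS <- dcamn / scale * active
    dA_cam <- array(as.vector(dS) %o% alpha, dim = dims)
  }

  w_ce <- if (config$loss_mode == "plain") 1 else config$w_ce
  dscores <- dscores * w_ce
  hb <- head_backward(model, A, dscores)
  dA <- hb$dA
  if (!is.null(dA_cam)) dA <- dA + config$w_cam * dA_cam
  layer_grads <- backward_features(model, fw$cache, dA)
  loss <- composite_loss(ce, cam_term, config)
  list(loss = loss,
       grads = collect_grads(model, layer_grads, list(dW = hb$dW, db = hb$db)),
       probs = p)
}

#' Train a model with the plain or lesion-based objective
#'
#' Mini-batch Adam optimization of the configured objective. In lesion mode
#' each image's Grad-CAM for its true class is computed during the forward
#' pass and the composite loss is backpropagated through the feature maps.
#' The model state at the best validation loss is returned, along with the
#' full per-epoch history. Fully deterministic given the seeds.
#'
#' @param model A `cam_cnn` model.
#' @param train_images,val_images Lists of `labeled_image` objects.
#' @param config A [training_config()].
#' @param label_fun Function mapping an image's `class_label` to one of
#'   `model$classes` (e.g. collapsing T1a/T1b to "EGC" for the detection
#'   task). Defaults to the identity.
#' @return A `cam_fit`: list with `model` (best-validation weights),
#'   `history` (tibble: epoch, ce, cam, total, val_loss, val_accuracy),
#'   `selected_epoch`, `config`.
#' @export
train_model <- function(model, train_images, val_images, config,
                        label_fun = identity) {
  stopifnot(inherits(model, "cam_cnn"), inherits(config, "training_config"))
  if (config$epochs > 0 &&
      (length(train_images) == 0 || length(val_images) == 0)) {
    abort("Training and validation sets must be non-empty.",
          class = "lesioncam_input_error")
  }
  prep <- function(imgs) {
    lapply(imgs, function(im) {
      lbl <- label_fun(im$class_label)
      yidx <- match(lbl, model$classes)
      if (is.na(yidx)) {
        abort(sprintf("Label '%s' is not a model class.", lbl),
              class = "lesioncam_input_error")
      }
      list(x = im$pixels, y = yidx, mask = im$lesion_mask)
    })
  }
  tr <- prep(train_images)
  va <- prep(val_images)

  if (config$epochs == 0L) {
    return(structure(list(model = model,
                          history = tibble::tibble(epoch = integer(),
                                                   ce = numeric(),
                                                   cam = numeric(),
                                                   total = numeric(),
                                                   val_loss = numeric(),
                                                   val_accuracy = numeric()),
                          selected_epoch = 0L, config = config),
                     class = "cam_fit"))
  }

  params <- get_params(model)
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best_val <- Inf
  best_params <- params
  best_epoch <- 1L
  hist <- vector("list", config$epochs)

  val_metrics <- function(model) {
    tot <- 0; acc <- 0
    for (d in va) {
      fw <- forward_features(model, d$x)
      p <- softmax(head_forward(model, fw$A))
      ce <- -log(max(p[d$y], 1e-12))
      cam_term <- 0
      if (config$loss_mode == "lesion") {
        uv <- dim(fw$A)[1:2]
        alpha <- model$head$W[, d$y] / prod(uv)
        S <- matrix(matrix(fw$A, prod(uv), dim(fw$A)[3]) %*% alpha,
                    uv[1], uv[2])
        camn <- normalize_cam(pmax(S, 0))$values
        msk <- if (!is.null(d$mask)) downsample_mask(d$mask, uv) else
          matrix(0, uv[1], uv[2])
        cam_term <- cam_localization_loss(camn, msk, method = config$cam_loss)
      }
      tot <- tot + composite_loss(ce, cam_term, config)$total
      acc <- acc + (which.max(p) == d$y)
    }
    c(loss = tot / length(va), acc = acc / length(va))
  }

  ys <- vapply(tr, function(d) d$y, integer(1))
  cls_freq <- table(ys)
  samp_w <- 1 / as.numeric(cls_freq[as.character(ys)])

  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      idx <- if (config$balance_classes) {
        sample(length(tr), length(tr), replace = TRUE, prob = samp_w)
      } else {
        sample(length(tr))
      }
      ep_ce <- 0; ep_cam <- 0; ep_tot <- 0
      for (start in seq(1, length(idx), by = config$batch_size)) {
        bidx <- idx[start:min(start + config$batch_size - 1, length(idx))]
        gsum <- NULL
        b_ce <- 0; b_cam <- 0; b_tot <- 0
        for (i in bidx) {
          d <- tr[[i]]
          st <- image_step(model, d$x, d$y, d$mask, config)
          b_ce <- b_ce + st$loss$ce_term
          b_cam <- b_cam + st$loss$cam_term
          b_tot <- b_tot + st$loss$total
          if (is.null(gsum)) gsum <- st$grads else {
            for (nm in names(gsum)) gsum[[nm]] <- gsum[[nm]] + st$grads[[nm]]
          }
        }
        nb <- length(bidx)
        if (!is.finite(b_tot)) {
          abort(sprintf("Non-finite training loss at epoch %d.", ep),
                class = "lesioncam_training_error")
        }
        step <- step + 1L
        for (nm in names(params)) {
          g <- gsum[[nm]] / nb
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
          mhat <- adam_m[[nm]] / (1 - beta1^step)
          vhat <- adam_v[[nm]] / (1 - beta2^step)
          params[[nm]] <- params[[nm]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
        model <- set_params(model, params)
        ep_ce <- ep_ce + b_ce; ep_cam <- ep_cam + b_cam; ep_tot <- ep_tot + b_tot
      }
      n_tr <- length(tr)
      vm <- val_metrics(model)
      hist[[ep]] <- tibble::tibble(epoch = ep, ce = ep_ce / n_tr,
                                   cam = ep_cam / n_tr, total = ep_tot / n_tr,
                                   val_loss = unname(vm["loss"]),
                                   val_accuracy = unname(vm["acc"]))
      if (vm["loss"] < best_val) {
        best_val <- vm["loss"]
        best_params <- params
        best_epoch <- ep
      }
    }
  })

  structure(list(model = set_params(model, best_params),
                 history = dplyr::bind_rows(hist),
                 selected_epoch = best_epoch, config = config),
            class = "cam_fit")
}

#' @export
print.cam_fit <- function(x, ...) {
  cat("<cam_fit> ", x$config$loss_mode, " objective, ",
      nrow(x$history), " epochs trained, selected epoch ",
      x$selected_epoch, "\n", sep = "")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat("  final: total ", signif(last$total, 4), ", val loss ",
        signif(last$val_loss, 4), ", val acc ",
        signif(last$val_accuracy, 4), "\n", sep = "")
  }
  invisible(x)
}
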