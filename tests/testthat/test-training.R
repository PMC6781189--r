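test_that("cross-entropy has the right closed forms", {
  expect_equal(cross_entropy(c(1, 0), 1), 0)
  expect_equal(cross_entropy(c(0.5, 0.5), 1), log(2))
  expect_equal(cross_entropy(c(0.1, 0.9), 1), -log(0.1))
  expect_equal(cross_entropy(rbind(c(0.1, 0.9), c(0.5, 0.5)), c(2, 1)),
               c(-log(0.9), log(2)))
  expect_error(cross_entropy(c(0.5, 0.5), 3),
               class = "lesioncam_input_error")
})

test_that("the localization loss is an exact MSE against the mask", {
  msk <- matrix(0, 4, 4); msk[2:3, 2:3] <- 1
  expect_equal(cam_localization_loss(msk, msk), 0)
  # all-zero CAM against a mask with fraction f of ones: loss = f
  expect_equal(cam_localization_loss(matrix(0, 4, 4), msk), 4 / 16)
  # all-ones CAM against a 4x4 mask with 4 ones: 12 mismatched cells
  expect_equal(cam_localization_loss(matrix(1, 4, 4), msk), 12 / 16)
  # absent mask = all-zero target
  expect_equal(cam_localization_loss(matrix(1, 2, 2), NULL), 1)
  expect_error(cam_localization_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)),
               class = "lesioncam_input_error")
  expect_error(cam_localization_loss(matrix(2, 2, 2), NULL),
               class = "lesioncam_input_error")
  # soft-Dice alternative: perfect match has zero loss
  expect_lt(cam_localization_loss(msk, msk, method = "dice"), 1e-6)
})

test_that("the composite loss respects mode and weights", {
  plain <- training_config("plain")
  lv <- composite_loss(0.7, 99, plain)
  expect_equal(lv$total, 0.7)
  expect_equal(lv$cam_term, 0)

  eq <- training_config("lesion", w_ce = 1, w_cam = 1)
  expect_equal(composite_loss(0.5, 0.25, eq)$total, 0.75)

  wt <- training_config("lesion", w_ce = 2, w_cam = 10)
  lv2 <- composite_loss(0.5, 0.25, wt)
  expect_equal(lv2$total, wt$w_ce * lv2$ce_term + wt$w_cam * lv2$cam_term)

  expect_error(training_config("lesion", w_ce = -1),
               class = "lesioncam_configuration_error")
  expect_error(training_config("lesion", w_ce = 0, w_cam = 0),
               class = "lesioncam_configuration_error")
})

make_toy_images <- function(n_per_class, side = 16, seed = 1) {
  # linearly separable brightness classes with a planted mask on the bright
  # class so lesion-mode code paths are exercised
  withr::with_seed(seed, {
    c(lapply(seq_len(n_per_class), function(i) {
      px <- array(runif(side * side * 3, 0, 0.35), c(side, side, 3))
      structure(list(image_id = paste0("dark", i), patient_id = "pd",
                     pixels = px, class_label = "nonEGC",
                     lesion_mask = NULL, quality_flags = character(0)),
                class = "labeled_image")
    }),
    lapply(seq_len(n_per_class), function(i) {
      px <- array(runif(side * side * 3, 0.65, 1), c(side, side, 3))
      msk <- matrix(FALSE, side, side)
      msk[4:9, 4:9] <- TRUE
      structure(list(image_id = paste0("bright", i), patient_id = "pb",
                     pixels = px, class_label = "T1a",
                     lesion_mask = msk, quality_flags = character(0)),
                class = "labeled_image")
    }))
  })
}

test_that("zero-epoch training is a no-op", {
  m <- build_model("tiny-test", input_side = 16, seed = 1,
                   classes = c("nonEGC", "EGC"))
  imgs <- make_toy_images(3)
  fit <- train_model(m, imgs, imgs, training_config("plain", epochs = 0),
                     label_fun = function(cl) if (cl == "nonEGC") "nonEGC" else "EGC")
  expect_identical(lesioncam:::get_params(fit$model),
                   lesioncam:::get_params(m))
  expect_equal(fit$selected_epoch, 0L)
  expect_equal(nrow(fit$history), 0L)
})

test_that("training is deterministic and the loss decomposition holds", {
  m <- build_model("tiny-test", input_side = 16, seed = 2,
                   classes = c("nonEGC", "EGC"))
  imgs <- make_toy_images(5, seed = 3)
  lf <- function(cl) if (cl == "nonEGC") "nonEGC" else "EGC"
  cfg <- training_config("lesion", epochs = 3, seed = 5, batch_size = 4)
  f1 <- train_model(m, imgs, imgs, cfg, label_fun = lf)
  f2 <- train_model(m, imgs, imgs, cfg, label_fun = lf)
  expect_identical(f1$history, f2$history)
  expect_true(f1$selected_epoch %in% f1$history$epoch)
  # loss decomposition on every logged epoch
  expect_equal(f1$history$total,
               cfg$w_ce * f1$history$ce + cfg$w_cam * f1$history$cam,
               tolerance = 1e-12)
})

test_that("lesion mode with zero CAM weight reproduces plain training", {
  m <- build_model("tiny-test", input_side = 16, seed = 4,
                   classes = c("nonEGC", "EGC"))
  imgs <- make_toy_images(4, seed = 6)
  lf <- function(cl) if (cl == "nonEGC") "nonEGC" else "EGC"
  fp <- train_model(m, imgs, imgs,
                    training_config("plain", epochs = 2, seed = 9),
                    label_fun = lf)
  fl <- train_model(m, imgs, imgs,
                    training_config("lesion", w_ce = 1, w_cam = 0,
                                    epochs = 2, seed = 9),
                    label_fun = lf)
  expect_equal(fp$history$total, fl$history$total, tolerance = 1e-12)
  expect_equal(lesioncam:::get_params(fp$model),
               lesioncam:::get_params(fl$model), tolerance = 1e-12)
})

test_that("a separable toy problem is learned to 100% training accuracy", {
  m <- build_model("tiny-test", input_side = 16, seed = 8,
                   classes = c("nonEGC", "EGC"))
  imgs <- make_toy_images(10, seed = 10)
  lf <- function(cl) if (cl == "nonEGC") "nonEGC" else "EGC"
  fit <- train_model(m, imgs, imgs,
                     training_config("plain", epochs = 20, seed = 1,
                                     batch_size = 4, learning_rate = 3e-3,
                                     balance_classes = FALSE),
                     label_fun = lf)
  pred <- predict(fit$model, imgs, type = "class")
  truth <- vapply(imgs, function(im) lf(im$class_label), character(1))
  expect_equal(mean(pred$.pred_class == truth), 1)
})
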