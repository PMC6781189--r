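test_that("confusion metrics match hand computation", {
  perfect <- confusion_metrics(c("p", "p", "n"), c("p", "p", "n"), "p")
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)

  # tp=3, fn=1, tn=2, fp=2
  truth <- c(rep("p", 4), rep("n", 4))
  pred <- c("p", "p", "p", "n", "p", "p", "n", "n")
  cm <- confusion_metrics(pred, truth, "p")
  expect_equal(cm$tp, 3); expect_equal(cm$fn, 1)
  expect_equal(cm$tn, 2); expect_equal(cm$fp, 2)
  expect_equal(cm$sensitivity, 75)
  expect_equal(cm$specificity, 50)
  expect_equal(cm$ppv, 60)
  expect_equal(cm$npv, 200 / 3, tolerance = 1e-9)

  # swapping the positive class swaps the paired rates
  sw <- confusion_metrics(pred, truth, "n")
  expect_equal(sw$sensitivity, cm$specificity)
  expect_equal(sw$specificity, cm$sensitivity)
  expect_equal(sw$ppv, cm$npv)
  expect_equal(sw$npv, cm$ppv)

  expect_error(confusion_metrics(character(0), character(0), "p"),
               class = "lesioncam_input_error")
})

test_that("confusion rates are percentages in [0, 100] or NA", {
  withr::with_seed(12, {
    for (i in 1:20) {
      truth <- sample(c("a", "b"), 15, replace = TRUE)
      pred <- sample(c("a", "b"), 15, replace = TRUE)
      if (length(unique(truth)) < 2) next
      cm <- confusion_metrics(pred, truth, "a")
      rates <- unlist(cm[c("sensitivity", "specificity", "ppv", "npv",
                           "accuracy")])
      expect_true(all(is.na(rates) | (rates >= 0 & rates <= 100)))
    }
  })
})

test_that("the ROC curve is well formed and AUC matches concordance", {
  r <- roc_curve_auc(c(0.9, 0.8, 0.2, 0.1), c("p", "p", "n", "n"), "p")
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))

  flat <- roc_curve_auc(rep(0.3, 10), rep(c("p", "n"), 5), "p")
  expect_equal(flat$auc, 0.5)

  withr::with_seed(14, {
    for (i in 1:20) {
      sc <- round(runif(40), 1)  # rounding forces ties
      lb <- sample(c("p", "n"), 40, replace = TRUE)
      if (length(unique(lb)) < 2) next
      expect_equal(roc_curve_auc(sc, lb, "p")$auc,
                   concordance_auc(sc, lb, "p"), tolerance = 1e-12)
    }
  })

  expect_error(roc_curve_auc(runif(5), rep("p", 5), "p"),
               class = "lesioncam_input_error")
})

test_that("AUC agrees with an independent ROC implementation", {
  withr::with_seed(21, {
    sc <- round(runif(60), 2)
    lb <- sample(c("p", "n"), 60, replace = TRUE)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_curve_auc(sc, lb, "p")$auc, ref, tolerance = 1e-12)
})

test_that("pooled-fold AUC equals AUC of the concatenated vectors", {
  withr::with_seed(15, {
    folds <- lapply(1:5, function(i) {
      tibble::tibble(score = runif(30),
                     label = sample(c("p", "n"), 30, replace = TRUE))
    })
  })
  pooled <- dplyr::bind_rows(folds)
  expect_equal(roc_curve_auc(pooled$score, pooled$label, "p")$auc,
               concordance_auc(pooled$score, pooled$label, "p"),
               tolerance = 1e-12)
})

test_that("activated-region extraction keeps the largest component", {
  msk <- matrix(0, 10, 10); msk[2:6, 2:7] <- 1
  expect_equal(localize_from_cam(msk) + 0, msk)

  expect_true(all(!localize_from_cam(matrix(0, 5, 5))))

  two <- matrix(0, 12, 12)
  two[1:6, 1:5] <- 0.9   # area 30
  two[9:10, 5:9] <- 0.9  # area 10, disjoint
  region <- localize_from_cam(two, threshold = 0.5)
  expect_equal(sum(region), 30)
  expect_true(all(region[1:6, 1:5]))

  expect_error(localize_from_cam(matrix(2, 3, 3)),
               class = "lesioncam_contract_error")
  raw <- compute_cam(build_model("tiny-test", input_side = 8, seed = 1),
                     array(runif(192), c(8, 8, 3)), 1)
  expect_error(localize_from_cam(raw),
               class = "lesioncam_contract_error")
})

test_that("overlap ratio is IoU with the empty-region conventions", {
  a <- matrix(FALSE, 6, 6); a[2:3, 2:3] <- TRUE
  expect_equal(overlap_ratio(a, a), 1)

  b <- matrix(FALSE, 6, 6); b[5:6, 5:6] <- TRUE
  expect_equal(overlap_ratio(a, b), 0)

  t4 <- matrix(FALSE, 6, 6); t4[1:4, 2:3] <- TRUE  # 4x2 containing the 2x2
  a2 <- matrix(FALSE, 6, 6); a2[2:3, 2:3] <- TRUE
  expect_equal(overlap_ratio(a2, t4), 4 / 8)

  none <- matrix(FALSE, 6, 6)
  expect_equal(overlap_ratio(none, none), 1)
  expect_equal(overlap_ratio(none, a), 0)
  expect_equal(overlap_ratio(a, none), 0)
  expect_equal(overlap_ratio(a2, t4, method = "iot"), 4 / 8)
  expect_error(overlap_ratio(a, matrix(FALSE, 5, 5)),
               class = "lesioncam_input_error")

  withr::with_seed(16, {
    for (i in 1:20) {
      r1 <- matrix(runif(36) > 0.5, 6, 6)
      r2 <- matrix(runif(36) > 0.5, 6, 6)
      ov <- overlap_ratio(r1, r2)
      expect_gte(ov, 0); expect_lte(ov, 1)
    }
  })
})

test_that("correct ratio counts overlaps at the cutoff", {
  expect_equal(correct_ratio(rep(1, 5)), 1)
  expect_equal(correct_ratio(c(0.6, 0.4)), 0.5)
  ovs <- c(runif(190, 0.5, 1), runif(10, 0, 0.49))
  expect_equal(correct_ratio(ovs), 0.95)
  expect_equal(correct_ratio(tibble::tibble(overlap = c(0.7, 0.2))), 0.5)
  expect_error(correct_ratio(numeric(0)), class = "lesioncam_input_error")
})

test_that("evaluation accounting multiplies out", {
  expect_equal(evaluation_totals(5, 300, 90), 1590)
  expect_equal(evaluation_totals(5, 660, 90), 3390)
  expect_equal(evaluation_totals(1, 0, 0), 0)
})
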