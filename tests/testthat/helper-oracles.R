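# Independent oracles and small fixture builders used across the suite.

# Brute-force Grad-CAM oracle: recompute the pooled-gradient weights alpha_k
# by central finite differences on each feature-map cell, pushing perturbed
# maps through an independently written head computation (global average
# pooling + dense layer, plain R), then assemble the rectified weighted sum.
fd_gradcam_oracle <- function(model, image, class_index, h = 1e-4) {
  x <- if (inherits(image, "labeled_image")) image$pixels else image
  A <- lesioncam:::forward_features(model, x)$A
  W <- model$head$W
  b <- model$head$b
  score_from_A <- function(A) {
    g <- apply(A, 3, mean)
    (drop(t(W) %*% g) + b)[class_index]
  }
  K <- dim(A)[3]
  alpha <- numeric(K)
  for (k in seq_len(K)) {
    gsum <- 0
    for (i in seq_len(dim(A)[1])) {
      for (j in seq_len(dim(A)[2])) {
        Ap <- A; Ap[i, j, k] <- Ap[i, j, k] + h
        Am <- A; Am[i, j, k] <- Am[i, j, k] - h
        gsum <- gsum + (score_from_A(Ap) - score_from_A(Am)) / (2 * h)
      }
    }
    alpha[k] <- gsum / prod(dim(A)[1:2])
  }
  S <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(K)) S <- S + alpha[k] * A[, , k]
  list(alpha = alpha, cam = pmax(S, 0))
}

# O(n^2) pairwise-concordance AUC with ties counted one half.
concordance_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive Fisher two-sided p: enumerate all tables with the observed
# margins, sum hypergeometric probabilities no greater than the observed
# table's (with a small relative tolerance for ties, as in the classical
# definition).
fisher_enumeration_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A small, fast synthetic cohort for structural tests.
tiny_cohort <- function(n_patients = 10, side = 32, seed = 42,
                        class_mix = c(nonEGC = 0.5, T1a = 0.25, T1b = 0.25)) {
  generate_cohort(n_patients, class_mix = class_mix,
                  images_per_patient = c(2L, 3L), image_side = side,
                  seed = seed)
}

luminance_of <- function(img) {
  0.299 * img$pixels[, , 1] + 0.587 * img$pixels[, , 2] +
    0.114 * img$pixels[, , 3]
}

# In-mask versus out-of-mask high-frequency contrast statistic used for the
# texture-monotonicity property.
texture_contrast_stat <- function(img) {
  lum <- 0.299 * img$pixels[, , 1] + 0.587 * img$pixels[, , 2] +
    0.114 * img$pixels[, , 3]
  hp <- lum - lesioncam:::gaussian_blur(lum, 1.5)
  abs(stats::var(hp[img$lesion_mask]) - stats::var(hp[!img$lesion_mask]))
}
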