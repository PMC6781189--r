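# Internal numeric helpers shared across modules.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

softmax <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

luminance <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

# Separable Gaussian blur implemented as banded-matrix products; exact and
# fast at the image sides used here (<= a few hundred pixels).
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- nrow(x)
  m <- ncol(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  band <- function(size) {
    B <- matrix(0, size, size)
    for (d in seq(-half, half)) {
      idx <- seq_len(size)
      src <- idx + d
      ok <- src >= 1 & src <= size
      B[cbind(idx[ok], src[ok])] <- B[cbind(idx[ok], src[ok])] + k[d + half + 1]
    }
    # renormalize rows so borders do not darken
    B / rowSums(B)
  }
  band(n) %*% x %*% t(band(m))
}

# Correlated (smoothed white) noise field with unit-ish scale.
smooth_noise <- function(n, m = n, sigma = 2) {
  z <- matrix(rnorm(n * m), n, m)
  z <- gaussian_blur(z, sigma)
  s <- stats::sd(as.vector(z))
  if (s > 0) z / s else z
}

# 3x3 binary dilation / erosion (8-neighbourhood) of a logical matrix.
dilate1 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  out <- mask
  shifts <- expand.grid(di = -1:1, dj = -1:1)
  for (r in seq_len(nrow(shifts))) {
    di <- shifts$di[r]; dj <- shifts$dj[r]
    if (di == 0 && dj == 0) next
    src_i <- pmin(pmax(seq_len(n) + di, 1L), n)
    src_j <- pmin(pmax(seq_len(m) + dj, 1L), m)
    out <- out | mask[src_i, src_j, drop = FALSE]
  }
  out
}

erode1 <- function(mask) !dilate1(!mask)

is_binary_matrix <- function(x) {
  is.matrix(x) && (is.logical(x) || all(x %in% c(0, 1)))
}

as_logical_mask <- function(x) {
  if (is.logical(x)) return(x)
  mode(x) <- "logical"
  x
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
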