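# Independent brute-force oracles, written against the definitions and
# kept free of the package's vectorised code paths.

# Energy-of-Laplacian by explicit double loop: normalize brightness over
# imaged (positive) pixels to mean 0.5, convolve the interior with the
# 5-point Laplacian, average the squared response, scale by calibration.
oracle_lape <- function(x, calibration = lape_calibration()) {
  imaged <- x[x > 0]
  x <- x * (0.5 / mean(imaged))
  n <- nrow(x); m <- ncol(x)
  total <- 0
  for (i in 2:(n - 1)) {
    for (j in 2:(m - 1)) {
      L <- x[i - 1, j] + x[i + 1, j] + x[i, j - 1] + x[i, j + 1] -
        4 * x[i, j]
      total <- total + L * L
    }
  }
  total / ((n - 2) * (m - 2)) * calibration
}

# Kruskal-Wallis H by direct rank computation with tie correction.
oracle_kruskal_H <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Logistic regression by hand-rolled iteratively reweighted least squares.
oracle_irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    z <- eta + (y - p) / W
    beta_new <- solve(crossprod(X, X * W), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.numeric(beta)
}

# Cohen's kappa from the closed form on a contingency table.
oracle_kappa <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  po <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  (po - pe) / (1 - pe)
}

# Drop patch metadata, keeping only the bare numeric matrix.
strip <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  x
}

# A reproducible strictly-positive random patch.
random_patch <- function(n = 65, seed = 1) {
  set.seed(seed)
  ao_patch(matrix(runif(n * n, 0.05, 1), n, n))
}

# A small rendered mosaic fixture.
mosaic_fixture <- function(seed = 1, ...) {
  generate_patch(scene_params(seed = seed, ...))$patch
}
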