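# Minimal CNN engine: batched im2col + BLAS GEMM forward/backward passes.
# Feature maps are stored column-major as (h*w*c) x n matrices; index of
# pixel (i, j, channel k) is i + (j-1)*h + (k-1)*h*w.

# im2col gather indices for a valid convolution: K x P matrix flattened,
# K = kern^2 * c_in patch entries, P = oh * ow output positions.
conv_indices <- function(h, w, c_in, kern) {
  oh <- h - kern + 1L; ow <- w - kern + 1L
  di <- rep(seq_len(kern), times = kern * c_in)
  dj <- rep(rep(seq_len(kern), each = kern), times = c_in)
  ch <- rep(seq_len(c_in), each = kern * kern)
  base <- (di - 1L) + (dj - 1L) * h + (ch - 1L) * h * w   # K offsets
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  pos <- (oi - 1L) + (oj - 1L) * h                        # P anchors
  idx <- outer(base + 1L, pos, `+`)                       # K x P
  list(idx = as.integer(idx), K = length(base), P = length(pos),
       oh = oh, ow = ow)
}

# 2x2/stride-2 max-pool gather indices: four disjoint index vectors of
# length oh * ow * c (trailing odd row/column dropped).
pool_indices <- function(h, w, c) {
  oh <- h %/% 2L; ow <- w %/% 2L
  oi <- rep(seq_len(oh), times = ow * c)
  oj <- rep(rep(seq_len(ow), each = oh), times = c)
  ch <- rep(seq_len(c), each = oh * ow)
  anchor <- (2L * oi - 2L) + (2L * oj - 2L) * h + (ch - 1L) * h * w
  offs <- c(0L, 1L, h, h + 1L)                 # (di, dj) in {0,1}^2
  list(idx = lapply(offs, function(o) anchor + o + 1L),
       oh = oh, ow = ow, c = c)
}

conv_forward <- function(X, layer, cache = TRUE) {
  ci <- layer$ci
  n <- ncol(X)
  Xcol <- X[ci$idx, , drop = FALSE]            # (K*P) x n
  dim(Xcol) <- c(ci$K, ci$P * n)
  Z <- crossprod(layer$W, Xcol) + layer$b      # F x (P*n)
  f <- ncol(layer$W)
  dim(Z) <- c(f, ci$P, n)
  out <- aperm(Z, c(2, 1, 3))
  dim(out) <- c(ci$P * f, n)
  list(out = out, Xcol = if (cache) Xcol else NULL)
}

conv_backward <- function(dOut, Xcol, X_nrow, layer) {
  ci <- layer$ci
  f <- ncol(layer$W)
  n <- length(dOut) / (ci$P * f)
  dim(dOut) <- c(ci$P, f, n)
  dZ <- aperm(dOut, c(2, 1, 3))
  dim(dZ) <- c(f, ci$P * n)
  dW <- Xcol %*% t(dZ)                          # K x F
  db <- rowSums(dZ)
  dXcol <- layer$W %*% dZ                       # K x (P*n)
  dim(dXcol) <- c(ci$K * ci$P, n)
  sums <- rowsum(dXcol, group = ci$idx)         # by sorted unique index
  dX <- matrix(0, X_nrow, n)
  dX[as.integer(rownames(sums)), ] <- sums
  list(dX = dX, dW = dW, db = db)
}

pool_forward <- function(X, pi) {
  x1 <- X[pi$idx[[1]], , drop = FALSE]
  x2 <- X[pi$idx[[2]], , drop = FALSE]
  x3 <- X[pi$idx[[3]], , drop = FALSE]
  x4 <- X[pi$idx[[4]], , drop = FALSE]
  out <- pmax(x1, x2, x3, x4)
  # first-maximum tie break
  amax <- matrix(4L, nrow(out), ncol(out))
  amax[x3 == out] <- 3L
  amax[x2 == out] <- 2L
  amax[x1 == out] <- 1L
  list(out = out, amax = amax)
}

pool_backward <- function(dOut, amax, pi, X_nrow) {
  n <- ncol(dOut)
  dX <- matrix(0, X_nrow, n)
  for (k in 1:4) {
    sel <- amax == k
    if (!any(sel)) next
    tmp <- matrix(0, nrow(dOut), n)
    tmp[sel] <- dOut[sel]
    dX[pi$idx[[k]], ] <- tmp
  }
  dX
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}
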