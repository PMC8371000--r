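#' CNN configuration
#'
#' Configuration of the compact CIFAR-style network: a stack of
#' convolution (valid, square kernels) / ReLU / 2x2 max-pool blocks
#' followed by fully connected ReLU layers and a 3-way softmax.  The
#' input is fixed at 65 x 65 grayscale — the native 50 um sampling-window
#' size — and inputs of any other size are conditioned with
#' [condition_input()].
#'
#' @param conv_blocks list of `(filters, kernel)` pairs; default three
#'   blocks of 8/16/32 filters with 5 x 5 kernels.
#' @param fc_widths widths of the hidden fully connected layers.
#' @param learning_rate,momentum SGD with momentum hyper-parameters.
#' @param batch_size mini-batch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on the monitoring loss
#'   (`Inf` disables early stopping).
#' @param class_weights `"balanced"` for inverse-frequency weights in the
#'   cross-entropy loss (the clinical grade mix is heavily skewed towards
#'   category 2), or `"none"`.
#' @param monitor_fraction fraction of training *subjects* held out to
#'   monitor generalization during training.
#' @param seed integer seed covering weight initialization and batch
#'   shuffling.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(conv_blocks = list(c(8, 5), c(16, 5), c(32, 5)),
                       fc_widths = 64, learning_rate = 0.01,
                       momentum = 0.9, batch_size = 32, epochs = 10,
                       patience = Inf,
                       class_weights = c("balanced", "none"),
                       monitor_fraction = 0.1, seed = 1L) {
  class_weights <- match.arg(class_weights)
  structure(list(input_side = 65L, n_classes = 3L,
                 conv_blocks = conv_blocks, fc_widths = fc_widths,
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience,
                 class_weights = class_weights,
                 monitor_fraction = monitor_fraction,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Condition a patch to the network input size
#'
#' Larger patches are trimmed to their central `side x side` pixels;
#' smaller ones are reflection-padded (mirrored) symmetrically, with the
#' extra row/column of an odd deficit added at the bottom/right.
#' Idempotent at the target size.
#'
#' @param patch an [ao_patch] or numeric matrix.
#' @param side target side in pixels (default 65).
#' @return The conditioned patch.
#' @export
condition_input <- function(patch, side = 65L) {
  p <- as_patch(patch)
  x <- unclass(p)
  for (axis in 1:2) {
    n <- dim(x)[axis]
    if (n > side) {
      lo <- (n - side) %/% 2L + 1L
      x <- if (axis == 1) x[lo:(lo + side - 1L), , drop = FALSE]
           else x[, lo:(lo + side - 1L), drop = FALSE]
    } else if (n < side) {
      deficit <- side - n
      before <- deficit %/% 2L
      after <- deficit - before
      if (before > n || after > n)
        stop("patch too small to mirror to ", side, " px", call. = FALSE)
      idx <- c(if (before) seq(before, 1L) else integer(0),
               seq_len(n),
               if (after) seq(n, n - after + 1L) else integer(0))
      x <- if (axis == 1) x[idx, , drop = FALSE]
           else x[, idx, drop = FALSE]
    }
  }
  rewrap_patch(x, p)
}

# Stack patches into a standardized (side^2 x n) matrix: each patch is
# conditioned to `side` and z-scored (constant patches map to zero).
patches_to_matrix <- function(patches, side = 65L) {
  X <- vapply(patches, function(p) {
    x <- as.numeric(unclass(condition_input(p, side)))
    s <- stats::sd(x)
    if (s == 0) s <- 1
    (x - mean(x)) / s
  }, numeric(side * side))
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  X
}

# Build layer list with He-initialised weights and cached gather indices.
cnn_init <- function(config) {
  side <- config$input_side
  h <- side; w <- side; c_in <- 1L
  layers <- list()
  for (blk in config$conv_blocks) {
    f <- as.integer(blk[1]); kern <- as.integer(blk[2])
    ci <- conv_indices(h, w, c_in, kern)
    W <- matrix(stats::rnorm(ci$K * f, 0, sqrt(2 / ci$K)), ci$K, f)
    layers[[length(layers) + 1L]] <-
      list(type = "conv", W = W, b = rep(0, f), ci = ci,
           in_dim = h * w * c_in)
    h <- ci$oh; w <- ci$ow; c_in <- f
    pi <- pool_indices(h, w, c_in)
    layers[[length(layers) + 1L]] <-
      list(type = "pool", pi = pi, in_dim = h * w * c_in)
    h <- pi$oh; w <- pi$ow
  }
  d <- h * w * c_in
  for (width in c(config$fc_widths, config$n_classes)) {
    W <- matrix(stats::rnorm(d * width, 0, sqrt(2 / d)), d, width)
    layers[[length(layers) + 1L]] <-
      list(type = "fc", W = W, b = rep(0, width), in_dim = d)
    d <- width
  }
  layers
}

cnn_forward <- function(layers, X, cache = FALSE) {
  acts <- if (cache) vector("list", length(layers))
  masks <- if (cache) vector("list", length(layers))
  for (l in seq_along(layers)) {
    lay <- layers[[l]]
    if (cache) acts[[l]] <- X
    if (lay$type == "conv") {
      cf <- conv_forward(X, lay, cache = cache)
      X <- pmax(cf$out, 0)
      if (cache) masks[[l]] <- list(Xcol = cf$Xcol, relu = cf$out > 0)
    } else if (lay$type == "pool") {
      pf <- pool_forward(X, lay$pi)
      X <- pf$out
      if (cache) masks[[l]] <- pf$amax
    } else {
      Z <- crossprod(lay$W, X) + lay$b
      if (l < length(layers)) {      # hidden fc: ReLU; final: raw logits
        X <- pmax(Z, 0)
        if (cache) masks[[l]] <- Z > 0
      } else X <- Z
    }
  }
  list(logits = X, acts = acts, masks = masks)
}

cnn_backward <- function(layers, fwd, dLogits) {
  grads <- vector("list", length(layers))
  dX <- dLogits
  for (l in rev(seq_along(layers))) {
    lay <- layers[[l]]
    Xin <- fwd$acts[[l]]
    if (lay$type == "fc") {
      if (l < length(layers)) dX <- dX * fwd$masks[[l]]
      grads[[l]] <- list(dW = Xin %*% t(dX), db = rowSums(dX))
      dX <- lay$W %*% dX
    } else if (lay$type == "pool") {
      dX <- pool_backward(dX, fwd$masks[[l]], lay$pi, lay$in_dim)
    } else {
      dX <- dX * fwd$masks[[l]]$relu
      cb <- conv_backward(dX, fwd$masks[[l]]$Xcol, lay$in_dim, lay)
      grads[[l]] <- list(dW = cb$dW, db = cb$db)
      dX <- cb$dX
    }
  }
  grads
}

#' Train the compact CNN grader
#'
#' Trains the network on labeled patches with SGD + momentum and
#' per-class-weighted cross-entropy.  A subject-wise slice of the
#' training set is held out to monitor generalization; the returned
#' history records loss and accuracy on both slices at every epoch.
#' Fully deterministic under the config seed.
#'
#' @param patches list of [ao_patch] (any size; conditioned to 65 px).
#' @param labels integer categories 1-3, one per patch (all three
#'   classes must be present).
#' @param subjects subject id per patch (used for the monitoring split);
#'   defaults to one pseudo-subject per patch.
#' @param config a [cnn_config()].
#' @return A `cnn_model` with `layers`, `config` and `history`.
#' @export
cnn_train <- function(patches, labels, subjects = NULL,
                      config = cnn_config()) {
  labels <- check_categories(labels)
  if (length(patches) != length(labels))
    stop("patches and labels lengths differ", call. = FALSE)
  if (!all(1:3 %in% labels))
    stop("all three categories must be present in the training data",
         call. = FALSE)
  if (is.null(subjects)) subjects <- sprintf("ps%06d", seq_along(patches))

  X <- patches_to_matrix(patches, config$input_side)
  n <- ncol(X)

  model <- with_seed(config$seed, {
    # subject-wise monitoring split
    subj <- unique(subjects)
    n_mon <- max(1L, round(length(subj) * config$monitor_fraction))
    n_mon <- min(n_mon, length(subj) - 1L)
    mon_subj <- if (length(subj) > 1) sample(subj, n_mon) else character(0)
    mon <- subjects %in% mon_subj
    if (!any(!mon)) mon[] <- FALSE
    Xtr <- X[, !mon, drop = FALSE]; ytr <- labels[!mon]
    Xmo <- X[, mon, drop = FALSE]; ymo <- labels[mon]

    cw <- if (config$class_weights == "balanced") {
      freq <- tabulate(ytr, 3) / length(ytr)
      w <- ifelse(freq > 0, 1 / (3 * freq), 0)
      w / sum(w * freq)            # normalised to mean weight 1
    } else rep(1, 3)

    layers <- cnn_init(config)
    vel <- lapply(layers, function(l)
      if (l$type == "pool") NULL
      else list(dW = 0 * l$W, db = 0 * l$b))

    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          train_accuracy = numeric(0),
                          monitor_loss = numeric(0),
                          monitor_accuracy = numeric(0))
    best <- list(loss = Inf, layers = layers, since = 0L)

    eval_slice <- function(layers, Xs, ys) {
      if (!length(ys)) return(c(NA_real_, NA_real_))
      P <- cnn_predict_matrix(layers, Xs, config$batch_size)
      eps <- 1e-12
      loss <- -mean(cw[ys] * log(P[cbind(ys, seq_along(ys))] + eps))
      c(loss, 100 * mean(max.col(t(P)) == ys))
    }

    for (epoch in seq_len(config$epochs)) {
      ord <- sample(ncol(Xtr))
      for (start in seq(1, length(ord), by = config$batch_size)) {
        ix <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        Xb <- Xtr[, ix, drop = FALSE]; yb <- ytr[ix]
        fwd <- cnn_forward(layers, Xb, cache = TRUE)
        P <- softmax_cols(fwd$logits)
        wsum <- sum(cw[yb])
        dLogits <- P * rep(cw[yb], each = 3)
        dLogits[cbind(yb, seq_along(yb))] <-
          dLogits[cbind(yb, seq_along(yb))] - cw[yb]
        dLogits <- dLogits / wsum
        grads <- cnn_backward(layers, fwd, dLogits)
        for (l in seq_along(layers)) {
          if (layers[[l]]$type == "pool") next
          vel[[l]]$dW <- config$momentum * vel[[l]]$dW -
            config$learning_rate * grads[[l]]$dW
          vel[[l]]$db <- config$momentum * vel[[l]]$db -
            config$learning_rate * grads[[l]]$db
          layers[[l]]$W <- layers[[l]]$W + vel[[l]]$dW
          layers[[l]]$b <- layers[[l]]$b + vel[[l]]$db
        }
      }
      tr <- eval_slice(layers, Xtr, ytr)
      mo <- eval_slice(layers, Xmo, ymo)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = tr[1], train_accuracy = tr[2],
        monitor_loss = mo[1], monitor_accuracy = mo[2]))
      track <- if (is.na(mo[1])) tr[1] else mo[1]
      if (track < best$loss) {
        best <- list(loss = track, layers = layers, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= config$patience) break
      }
    }
    list(layers = best$layers, history = history)
  })

  structure(list(layers = model$layers, config = config,
                 history = model$history),
            class = "cnn_model")
}

# Batched forward returning a 3 x n probability matrix.
cnn_predict_matrix <- function(layers, X, batch_size = 64L) {
  n <- ncol(X)
  out <- matrix(0, 3, n)
  for (start in seq(1, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    out[, ix] <- softmax_cols(
      cnn_forward(layers, X[, ix, drop = FALSE])$logits)
  }
  out
}

#' Predict grade categories with a trained CNN
#'
#' @param model a `cnn_model` from [cnn_train()].
#' @param patches a single [ao_patch] or a list of them.
#' @return List with `category` (integer vector, argmax of the softmax)
#'   and `probabilities` (n x 3 matrix, rows summing to 1), in input
#'   order.
#' @export
cnn_predict <- function(model, patches) {
  if (!inherits(model, "cnn_model") || is.null(model$layers))
    stop("`model` must be a trained cnn_model", call. = FALSE)
  if (!is.list(patches) || inherits(patches, "ao_patch"))
    patches <- list(patches)
  X <- patches_to_matrix(patches, model$config$input_side)
  P <- cnn_predict_matrix(model$layers, X, model$config$batch_size)
  list(category = as.integer(max.col(t(P))),
       probabilities = t(P))
}

#' @export
print.cnn_model <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(l)
    if (l$type == "pool") 0L else length(l$W) + length(l$b), integer(1)))
  cat(sprintf("<cnn_model> %d layers, %d parameters, %d epoch(s) trained\n",
              length(x$layers), n_par, nrow(x$history)))
  invisible(x)
}
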