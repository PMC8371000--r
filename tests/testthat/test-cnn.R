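test_that("input conditioning crops, mirrors and is idempotent", {
  p65 <- random_patch(65, seed = 1)
  expect_identical(strip(condition_input(p65)), strip(p65))

  p71 <- random_patch(71, seed = 2)
  out <- condition_input(p71)
  expect_equal(dim(out), c(65L, 65L))
  expect_identical(strip(out), strip(p71)[4:68, 4:68])

  p61 <- random_patch(61, seed = 3)
  out2 <- condition_input(p61)
  expect_equal(dim(out2), c(65L, 65L))
  # 2-px mirror border: first padded row reflects the second original row
  expect_identical(out2[1, 3:63], strip(p61)[2, 1:61])
  expect_identical(out2[3:63, 1], strip(p61)[1:61, 2])
  # odd deficit: extra column goes to the right
  p62 <- random_patch(62, seed = 4)
  out3 <- condition_input(p62)
  expect_equal(dim(out3), c(65L, 65L))
  expect_identical(out3[2:63, 2:63], strip(p62))
  expect_identical(strip(condition_input(condition_input(p71))),
                   strip(condition_input(p71)))
})

test_that("network gradients match finite differences", {
  cfg <- cnn_config(conv_blocks = list(c(2, 3)), fc_widths = 4, seed = 3)
  cfg$input_side <- 9L
  layers <- aoqc:::with_seed(3, aoqc:::cnn_init(cfg))
  set.seed(10)
  X <- matrix(rnorm(81 * 2), 81, 2)
  y <- c(1L, 3L)
  lossfun <- function(lys) {
    P <- aoqc:::softmax_cols(aoqc:::cnn_forward(lys, X)$logits)
    -mean(log(P[cbind(y, 1:2)]))
  }
  fwd <- aoqc:::cnn_forward(layers, X, cache = TRUE)
  P <- aoqc:::softmax_cols(fwd$logits)
  dL <- P; dL[cbind(y, 1:2)] <- dL[cbind(y, 1:2)] - 1; dL <- dL / 2
  gr <- aoqc:::cnn_backward(layers, fwd, dL)
  eps <- 1e-6
  for (l in seq_along(layers)) {
    if (layers[[l]]$type == "pool") next
    for (trial in 1:4) {
      i <- sample(length(layers[[l]]$W), 1)
      l2 <- layers; l2[[l]]$W[i] <- l2[[l]]$W[i] + eps
      num <- (lossfun(l2) - lossfun(layers)) / eps
      expect_equal(gr[[l]]$dW[i], num, tolerance = 1e-4)
    }
  }
})

test_that("the network memorizes a three-patch training set", {
  patches <- lapply(1:3, function(k) mosaic_fixture(seed = k))
  patches <- rep(patches, 10)
  labels <- rep(1:3, 10)
  cfg <- cnn_config(conv_blocks = list(c(4, 5), c(8, 5)), fc_widths = 16,
                    epochs = 5, batch_size = 10, learning_rate = 0.05,
                    monitor_fraction = 0.001, seed = 2)
  model <- cnn_train(patches, labels, config = cfg)
  pred <- cnn_predict(model, patches)
  expect_equal(pred$category, labels)
  expect_equal(nrow(model$history), 5)
  expect_true(all(c("train_loss", "monitor_loss") %in%
                    names(model$history)))
})

test_that("predictions are normalized, ordered and deterministic", {
  patches <- lapply(1:3, function(k) mosaic_fixture(seed = k))
  cfg <- cnn_config(conv_blocks = list(c(4, 5)), fc_widths = 8,
                    epochs = 1, monitor_fraction = 0.001, seed = 7)
  model <- cnn_train(rep(patches, 3), rep(1:3, 3), config = cfg)
  pred <- cnn_predict(model, patches)
  expect_equal(rowSums(pred$probabilities), rep(1, 3), tolerance = 1e-6)
  expect_length(pred$category, 3)
  # batch order contract + determinism under the same seed
  pred_rev <- cnn_predict(model, rev(patches))
  expect_equal(pred_rev$category, rev(pred$category))
  model2 <- cnn_train(rep(patches, 3), rep(1:3, 3), config = cfg)
  expect_equal(model$layers, model2$layers)
  expect_error(cnn_predict(list(layers = NULL), patches), "trained")
  expect_error(cnn_train(patches, 1:2), "lengths differ")
  expect_error(cnn_train(patches[1:2], c(1L, 2L)), "three categories")
})
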