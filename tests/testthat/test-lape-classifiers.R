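test_that("the linear model recovers a planted line and separable clusters", {
  # two-point interpolation through (0,1) and (75,3)
  m <- fit_linear_model(c(0, 75, 0, 75, 37.5), c(1, 3, 1, 3, 2))
  expect_equal(m$slope, 2 / 75, tolerance = 1e-9)
  expect_equal(m$intercept, 1, tolerance = 1e-9)

  # closed-form OLS check: slope = Sxy/Sxx, intercept = ybar - slope*xbar
  set.seed(21)
  x <- runif(90, 0, 75)
  y <- sample(1:3, 90, replace = TRUE)
  m2 <- fit_linear_model(x, y)
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(m2$slope, sl, tolerance = 1e-9)
  expect_equal(m2$intercept, mean(y) - sl * mean(x), tolerance = 1e-9)
  expect_equal(sort(c((1.5 - m2$intercept) / m2$slope,
                      (2.5 - m2$intercept) / m2$slope)),
               m2$implied_thresholds)

  # well-separated clusters classify their own training data perfectly
  set.seed(2)
  sc <- c(rnorm(50, 3, 1), rnorm(50, 20, 1), rnorm(50, 60, 1))
  lb <- rep(1:3, each = 50)
  m3 <- fit_linear_model(sc, lb)
  expect_equal(accuracy(confusion(lb, predict_linear(m3, sc))), 100)
  expect_error(fit_linear_model(rep(1, 9), rep(1:3, 3)), "constant")
  expect_error(fit_linear_model(c(1, 2), c(1, 2)), "three categories")
})

test_that("linear predictions round half-up and clamp to the grade range", {
  m <- structure(list(slope = 1, intercept = 0), class = "lape_linear")
  expect_equal(predict_linear(m, 2.4), 2L)
  expect_equal(predict_linear(m, 2.5), 3L)
  expect_equal(predict_linear(m, 0.2), 1L)
  expect_equal(predict_linear(m, 3.9), 3L)
  # a model whose implied boundaries are (8, 35) puts 20 in category 2
  slope <- 1 / 27; intercept <- 1.5 - 8 / 27
  m2 <- structure(list(slope = slope, intercept = intercept),
                  class = "lape_linear")
  expect_equal(predict_linear(m2, 20), 2L)
  expect_equal(predict_linear(m2, 7.9), 1L)
  expect_equal(predict_linear(m2, 35.1), 3L)
})

test_that("the forest is deterministic under seed and separates clusters", {
  set.seed(5)
  sc <- c(rnorm(60, 3, 1), rnorm(60, 20, 1), rnorm(60, 60, 1))
  lb <- rep(1:3, each = 60)
  f1 <- fit_random_forest(sc, lb, n_trees = 300, seed = 11)
  f2 <- fit_random_forest(sc, lb, n_trees = 300, seed = 11)
  grid <- data.frame(score = seq(0, 75, by = 1))
  p1 <- stats::predict(f1$forest, data = grid)$predictions
  p2 <- stats::predict(f2$forest, data = grid)$predictions
  expect_identical(p1, p2)
  pred <- max.col(stats::predict(
    f1$forest, data = data.frame(score = sc))$predictions)
  expect_gte(mean(pred == lb), 0.99)
})

test_that("probability curves live on the 751-point grid and sum to 1", {
  set.seed(6)
  sim <- simulate_lape_scores(600, seed = 8)
  f <- fit_random_forest(sim$score, sim$category, n_trees = 200, seed = 3)
  cur <- probability_curves(f)
  expect_length(cur$grid, 751)
  expect_equal(cur$grid[2] - cur$grid[1], 0.1)
  expect_equal(rowSums(cur$raw), rep(1, 751), tolerance = 1e-6)
  # smoothed curves dominate only inside their own band on separable data
  set.seed(7)
  sc <- c(runif(80, 0, 6), runif(120, 12, 30), runif(100, 44, 70))
  lb <- rep(1:3, c(80, 120, 100))
  fs <- fit_random_forest(sc, lb, n_trees = 300, seed = 5)
  cs <- probability_curves(fs)
  dominant <- max.col(cs$smooth)
  expect_true(all(dominant[cs$grid < 4] == 1))
  expect_true(all(dominant[cs$grid > 14 & cs$grid < 28] == 2))
  expect_true(all(dominant[cs$grid > 46 & cs$grid < 68] == 3))
})

test_that("threshold extraction interpolates the curve crossings", {
  # hand-built curves with exact crossings at 8 and 35
  grid <- seq(0, 75, by = 0.1)
  p1 <- stats::plogis((8 - grid) * 2)
  p3 <- stats::plogis((grid - 35) * 2)
  p2 <- 1 - p1 - p3
  curves <- structure(list(grid = grid,
                           raw = cbind(`1` = p1, `2` = p2, `3` = p3),
                           smooth = cbind(`1` = p1, `2` = p2, `3` = p3)),
                      class = "probability_curves")
  th <- estimate_thresholds(curves)
  expect_equal(th$t12, 8, tolerance = 0.05)
  expect_equal(th$t23, 35, tolerance = 0.05)

  # planted crossings at 7 and 38
  q1 <- stats::plogis((7 - grid) * 2)
  q3 <- stats::plogis((grid - 38) * 2)
  curves2 <- structure(list(grid = grid,
                            raw = cbind(`1` = q1, `2` = 1 - q1 - q3,
                                        `3` = q3),
                            smooth = cbind(`1` = q1, `2` = 1 - q1 - q3,
                                           `3` = q3)),
                       class = "probability_curves")
  th2 <- estimate_thresholds(curves2)
  expect_equal(th2$t12, 7, tolerance = 0.05)
  expect_equal(th2$t23, 38, tolerance = 0.05)

  # class 1 dominant everywhere -> no intersection -> error
  flat <- structure(list(grid = grid,
                         raw = cbind(`1` = rep(0.8, 751),
                                     `2` = rep(0.15, 751),
                                     `3` = rep(0.05, 751)),
                         smooth = cbind(`1` = rep(0.8, 751),
                                        `2` = rep(0.15, 751),
                                        `3` = rep(0.05, 751))),
                    class = "probability_curves")
  expect_error(estimate_thresholds(flat), "intersect")
})

test_that("threshold classification uses strict outer bands", {
  th <- lape_thresholds(8, 35)
  expect_equal(classify_by_thresholds(5, th), 1L)
  expect_equal(classify_by_thresholds(8, th), 2L)   # boundary -> middle
  expect_equal(classify_by_thresholds(35, th), 2L)
  expect_equal(classify_by_thresholds(20, th), 2L)
  expect_equal(classify_by_thresholds(40, lape_thresholds(7, 38)), 3L)
  # monotone nondecreasing in the score
  sc <- seq(0, 75, by = 0.5)
  expect_true(all(diff(classify_by_thresholds(sc, th)) >= 0))
  expect_error(lape_thresholds(35, 8), "t12 < t23")
})

test_that("planted score simulation pins its decision boundaries", {
  sim <- simulate_lape_scores(5000, seed = 1)
  expect_true(all(sim$score >= 0 & sim$score <= 75))
  expect_true(all(sim$category %in% 1:3))
  # class-conditional means sit at the prior-corrected placement
  # (0, 16.75, 52.91); clipping at 0 lifts the class-1 mean to ~1.2
  means <- as.numeric(tapply(sim$score, sim$category, mean))
  expect_lt(abs(means[1] - 1.2), 0.3)
  expect_lt(abs(means[2] - 16.75), 0.3)
  expect_lt(abs(means[3] - 52.91), 0.3)
  # realized class mix tracks the default 25/50/25 priors
  props <- as.numeric(table(sim$category)) / 5000
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 0.03))
  expect_identical(sim, simulate_lape_scores(5000, seed = 1))
})
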