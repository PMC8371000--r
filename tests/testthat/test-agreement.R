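test_that("adjudication follows unanimity, majority, then the senior grader", {
  g <- c("expert", "intermediate", "beginner")
  expect_equal(adjudicate(c(3, 3, 3), g, "expert"), 3L)
  expect_equal(adjudicate(c(2, 3, 3), g, "expert"), 3L)
  expect_equal(adjudicate(c(1, 2, 3), g, "intermediate"), 2L)
  expect_true(is.na(adjudicate(c(1, 2, 3), g, "expert",
                               on_split = "flag")))
  expect_error(adjudicate(c(1, 2), c("a", "a"), "a"), "duplicate")
  expect_error(adjudicate(c(1, 2), c("a", "b"), "c"), "senior")
})

test_that("confusion matrices count label pairs exactly", {
  x <- c(1, 2, 3, 2, 1, 3, 2, 2, 1)
  cm <- confusion(x, x)
  expect_equal(sum(diag(unclass(cm))), length(x))
  expect_equal(accuracy(cm), 100)

  ref <- rep(2L, 7)
  cm2 <- confusion(ref, rep(3L, 7))
  expect_equal(unclass(cm2)["2", "3"], 7L)
  expect_equal(accuracy(cm2), 0)

  # hand-enumerated pair
  ref <- c(1, 1, 2, 2, 2, 3, 3, 3, 3)
  pred <- c(1, 2, 2, 2, 3, 3, 3, 1, 2)
  cm3 <- unclass(confusion(ref, pred))
  expect_equal(cm3["1", ], c(`1` = 1L, `2` = 1L, `3` = 0L))
  expect_equal(cm3["2", ], c(`1` = 0L, `2` = 2L, `3` = 1L))
  expect_equal(cm3["3", ], c(`1` = 1L, `2` = 1L, `3` = 2L))
  expect_equal(accuracy(confusion(ref, pred)), 100 * 5 / 9)
  expect_error(confusion(1:3, 1:2), "lengths differ")
})

test_that("row and column sums give class counts", {
  set.seed(31)
  ref <- sample(1:3, 200, replace = TRUE)
  pred <- sample(1:3, 200, replace = TRUE)
  cm <- unclass(confusion(ref, pred))
  expect_equal(rowSums(cm), c(`1` = sum(ref == 1), `2` = sum(ref == 2),
                              `3` = sum(ref == 3)))
  expect_equal(colSums(cm), c(`1` = sum(pred == 1), `2` = sum(pred == 2),
                              `3` = sum(pred == 3)))
})

test_that("kappa agrees with the closed form and an independent package", {
  # 2x2 contingency ((20,5),(10,15)) on categories {1,2}
  a <- rep(c(1, 1, 2, 2), c(20, 5, 10, 15))
  b <- rep(c(1, 2, 1, 2), c(20, 5, 10, 15))
  # p_o = 35/50 = 0.70, p_e = 0.5*0.6 + 0.5*0.4 = 0.50 -> kappa = 0.4
  expect_equal(cohens_kappa(a, b), 0.4, tolerance = 1e-9)
  expect_equal(cohens_kappa(a, b), oracle_kappa(a, b), tolerance = 1e-12)
  skip_if_not_installed("e1071")
  expect_equal(cohens_kappa(a, b),
               e1071::classAgreement(table(a, b))$kappa,
               tolerance = 1e-12)
})

test_that("kappa is 1 on identical ratings and ~0 on independent ones", {
  x <- c(1, 2, 3, 2, 1, 3)
  expect_equal(cohens_kappa(x, x), 1)
  set.seed(12)
  a <- sample(1:3, 10000, replace = TRUE)
  b <- sample(1:3, 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(a, b)), 0.05)
})

test_that("kappa is symmetric and invariant to common relabelling", {
  set.seed(13)
  a <- sample(1:3, 300, replace = TRUE)
  b <- pmin(pmax(a + sample(c(-1, 0, 0, 1), 300, replace = TRUE), 1), 3)
  expect_equal(cohens_kappa(a, b), cohens_kappa(b, a))
  perm <- c(3L, 1L, 2L)
  expect_equal(cohens_kappa(perm[a], perm[b]), cohens_kappa(a, b))
})

test_that("identical constant raters give kappa 1, not an error", {
  expect_equal(cohens_kappa(rep(2, 5), rep(2, 5)), 1)
  expect_error(cohens_kappa(rep(2, 5), c(2, 2, 2, 2, 2) * 0 + 2), NA)
})

test_that("subject-wise splits are disjoint, complete and deterministic", {
  man <- data.frame(subject = rep(sprintf("S%02d", 1:50), each = 4))
  sp <- subjectwise_split(man, 23 / 50, seed = 5)
  expect_length(sp$train, 23)
  expect_length(sp$validation, 27)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), unique(man$subject))
  expect_identical(sp, subjectwise_split(man, 23 / 50, seed = 5))
  # both sides keep at least one subject even at extreme fractions
  man2 <- data.frame(subject = c("a", "a", "b"))
  sp2 <- subjectwise_split(man2, 0.99, seed = 1)
  expect_length(sp2$train, 1)
  expect_length(sp2$validation, 1)
  expect_error(subjectwise_split(man, 1.2), "train_fraction")
})

test_that("k-fold CV partitions subjects and scores separable data at 100%", {
  set.seed(44)
  man <- data.frame(
    subject = rep(sprintf("S%02d", 1:20), each = 10),
    true_category = 0L, score = 0)
  cat_of <- rep(sample(rep(1:3, length.out = 20)), each = 10)
  man$true_category <- cat_of
  man$score <- c(5, 20, 50)[cat_of] + runif(200, -2, 2)
  fit <- function(train) lape_thresholds(12, 35)
  pred <- function(model, test) classify_by_thresholds(test$score, model)
  cv <- kfold_cv(man, k = 10, fit, pred, seed = 2)
  expect_length(cv$fold_accuracy, 10)
  expect_equal(cv$mean_accuracy, 100)
  expect_identical(cv, kfold_cv(man, k = 10, fit, pred, seed = 2))
  expect_error(kfold_cv(man, k = 25, fit, pred), "exceeds")
})

test_that("Kruskal-Wallis matches brute-force ranks and behaves under the null", {
  v <- c(1, 2, 3, 10, 20, 30, 100, 200, 300)
  g <- rep(1:3, each = 3)
  res <- kruskal_wallis_by_category(v, g)
  expect_equal(res$H, oracle_kruskal_H(v, g), tolerance = 1e-12)
  expect_equal(res$df, 2)
  # fully separated groups attain the maximal H for n=9, k=3:
  # mean ranks (2, 5, 8) -> H = 12/90 * 3*(4+25+64) - 30 = 7.2
  expect_equal(res$H, 7.2, tolerance = 1e-12)

  set.seed(77)
  pvals <- replicate(100, {
    kruskal_wallis_by_category(rnorm(300),
                               sample(1:3, 300, TRUE))$p_value
  })
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("category-separated scores give a decisive Kruskal-Wallis result", {
  set.seed(9)
  labels <- sample(1:3, 400, replace = TRUE)
  scores <- c(3, 18, 45)[labels] + rnorm(400, 0, 4)
  expect_lt(kruskal_wallis_by_category(scores, labels)$p_value, 0.001)
})
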