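make_factor_fixture <- function(n = 200, seed = 1,
                                beta = c(disease = log(5.2),
                                         ecc = log(1.03),
                                         age = log(1.03))) {
  set.seed(seed)
  meta <- data.frame(
    subject = sprintf("S%03d", rep(1:(n / 4), each = 4)[1:n]),
    group = sample(c("healthy", "DSM", "HCQ"), n, TRUE, c(0.5, 0.25, 0.25)),
    eccentricity_deg = sample(1:10, n, TRUE),
    age = runif(n, 25, 85),
    axial_length = rnorm(n, 23.7, 0.9),
    spherical_equivalent = rnorm(n, 0, 1.5),
    bcva = rnorm(n, 88, 5),
    bcea63 = abs(rnorm(n, 1.5, 1.2)) + 0.05)
  eta <- -2 + beta[["disease"]] * (meta$group != "healthy") +
    beta[["ecc"]] * meta$eccentricity_deg +
    beta[["age"]] * (meta$age - 57)
  meta$true_category <- ifelse(runif(n) < plogis(eta), 2L, 3L)
  meta
}

test_that("logistic coefficients match an IRLS oracle to 1e-6", {
  meta <- make_factor_fixture(200, seed = 5)
  fit <- fit_quality_logistic(meta)
  X <- cbind(1, as.integer(meta$group != "healthy"),
             meta$eccentricity_deg, meta$age, meta$axial_length,
             meta$spherical_equivalent, meta$bcva, meta$bcea63)
  beta_oracle <- oracle_irls_logistic(X, as.integer(meta$true_category == 2L))
  expect_equal(fit$report$estimate, beta_oracle, tolerance = 1e-6)
  # OR transform is exactly exp(coefficient), CI brackets the OR
  expect_equal(fit$report$odds_ratio, exp(fit$report$estimate))
  expect_true(all(fit$report$ci_low < fit$report$odds_ratio &
                    fit$report$odds_ratio < fit$report$ci_high))
})

test_that("degenerate outcomes and missing columns are rejected", {
  meta <- make_factor_fixture(60, seed = 2)
  meta$true_category <- 3L
  expect_error(fit_quality_logistic(meta), "both outcome classes")
  expect_error(fit_quality_logistic(data.frame(true_category = 2:3)),
               "lacks columns")
})

test_that("category-1 patches are excluded and do not move the estimates", {
  meta <- make_factor_fixture(300, seed = 8)
  fit0 <- fit_quality_logistic(meta)
  extra <- meta[1:40, ]
  extra$true_category <- 1L
  suppressMessages(fit1 <- fit_quality_logistic(rbind(meta, extra)))
  expect_equal(fit0$report$estimate, fit1$report$estimate, tolerance = 1e-12)
})

test_that("location frequencies count poor patches among analyzable ones", {
  man <- data.frame(
    true_category = c(rep(3L, 4), rep(2L, 3), 3L, rep(2L, 2), 1L),
    eccentricity_deg = c(rep(4, 4), rep(6, 4), 11, 11, 6),
    group = "healthy")
  tab <- category_frequency_by_location(man)
  expect_equal(tab$fraction_category2[tab$eccentricity_deg == 4], 0)
  expect_equal(tab$fraction_category2[tab$eccentricity_deg == 6], 0.75)
  expect_false(11 %in% tab$eccentricity_deg)   # beyond 10 degrees excluded
  # invariant to patch order and to the presence of category-1 rows
  man2 <- man[sample(nrow(man)), ]
  tab2 <- category_frequency_by_location(man2)
  expect_equal(tab[order(tab$eccentricity_deg), ],
               tab2[order(tab2$eccentricity_deg), ],
               ignore_attr = TRUE)
})

test_that("per-subject poor fractions use the inclusive half-or-more rule", {
  man <- data.frame(
    subject = rep(c("a", "b", "c"), times = c(20, 10, 2)),
    true_category = c(rep(2L, 10), rep(3L, 10),   # a: exactly half
                      rep(3L, 10),                # b: none poor
                      rep(1L, 2)))                # c: no analyzable patches
  res <- suppressWarnings(subject_fraction_poor(man))
  expect_equal(res$per_subject$fraction_category2[
    res$per_subject$subject == "a"], 0.5)
  expect_equal(res$share_half_or_more, 0.5)      # a counts, b does not
  expect_warning(subject_fraction_poor(man), "no analyzable")
  all3 <- data.frame(subject = rep("s", 5), true_category = rep(3L, 5))
  expect_equal(subject_fraction_poor(all3)$share_half_or_more, 0)
})

test_that("planted cohort share of poor-dominated subjects is recovered", {
  coh <- generate_cohort(80, category_mix = c(0.1, 0.63, 0.27), seed = 17,
                         render = FALSE)
  res <- subject_fraction_poor(coh$manifest)
  # patch-level poor rate 0.7 among analyzable; most subjects cross 0.5
  expect_gt(res$share_half_or_more, 0.6)
  expect_equal(nrow(res$per_subject), 80)
})

test_that("confidence intervals tighten with sample size", {
  fit_small <- fit_quality_logistic(make_factor_fixture(200, seed = 3))
  fit_big <- fit_quality_logistic(make_factor_fixture(3200, seed = 3))
  width <- function(f) log(f$report$ci_high[2]) - log(f$report$ci_low[2])
  expect_lt(width(fit_big), 0.5 * width(fit_small))
})
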