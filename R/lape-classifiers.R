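check_training <- function(scores, labels) {
  labels <- check_categories(labels)
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ", call. = FALSE)
  if (length(unique(scores)) < 2)
    stop("degenerate design: scores are constant", call. = FALSE)
  if (!all(1:3 %in% labels))
    stop("all three categories must be represented in training data",
         call. = FALSE)
  labels
}

#' Linear-regression grade classifier
#'
#' Ordinary least-squares fit of the numeric grade (1, 2, 3) on the LAPE
#' score.  Prediction rounds the fitted value to the nearest integer
#' grade ([predict_linear()]); the score values at which the fitted line
#' crosses 1.5 and 2.5 are the classifier's implied category boundaries,
#' exposed as `implied_thresholds`.
#'
#' @param scores numeric LAPE scores.
#' @param labels categories 1-3 (all three present).
#' @return A `lape_linear` model with `slope`, `intercept` and
#'   `implied_thresholds`.
#' @export
fit_linear_model <- function(scores, labels) {
  labels <- check_training(scores, labels)
  fit <- stats::lm(y ~ x, data = data.frame(x = scores, y = labels))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  implied <- if (abs(slope) > .Machine$double.eps)
    sort(c((1.5 - intercept) / slope, (2.5 - intercept) / slope))
  else c(NA_real_, NA_real_)
  structure(list(slope = slope, intercept = intercept,
                 implied_thresholds = implied),
            class = "lape_linear")
}

#' @rdname fit_linear_model
#' @param model a fitted `lape_linear` model.
#' @param score LAPE score(s) to classify.
#' @details Rounding of half-integers is half-up (2.5 becomes 3), fixed
#'   for determinism; fitted values are clamped to the 1-3 grade range.
#' @return `predict_linear()` returns integer categories.
#' @export
predict_linear <- function(model, score) {
  stopifnot(inherits(model, "lape_linear"))
  yhat <- model$slope * score + model$intercept
  cls <- floor(yhat + 0.5)          # round half-up
  as.integer(pmin(pmax(cls, 1), 3))
}

#' Random-forest grade classifier on the LAPE score
#'
#' A 1,000-tree probability random forest (ranger engine) on the single
#' LAPE feature.  Deterministic under `seed` (single-threaded).
#'
#' @inheritParams fit_linear_model
#' @param n_trees number of trees (default 1000).
#' @param seed integer seed.
#' @return A `lape_forest` model wrapping the ranger fit.
#' @export
fit_random_forest <- function(scores, labels, n_trees = 1000, seed = 1L) {
  labels <- check_training(scores, labels)
  dat <- data.frame(score = scores,
                    category = factor(labels, levels = 1:3))
  fit <- ranger::ranger(category ~ score, data = dat,
                        num.trees = n_trees, probability = TRUE,
                        seed = as.integer(seed), num.threads = 1L)
  structure(list(forest = fit, n_trees = n_trees, seed = as.integer(seed)),
            class = "lape_forest")
}

#' Class-probability curves over the LAPE axis
#'
#' Evaluates the forest's class probabilities on the working LAPE grid —
#' 0 to 75 in 0.1 steps, 751 points — and smooths each class's curve with
#' loess.  The smoothed curves are what the threshold-extraction rule
#' intersects.
#'
#' @param model a `lape_forest` model.
#' @param loess_span loess smoothing span over the grid (default 0.3).
#' @param grid_max,grid_step grid geometry (defaults 75 and 0.1).
#' @return A `probability_curves` list: `grid`, `raw` (751 x 3 matrix,
#'   rows summing to 1) and `smooth` (same shape).
#' @export
probability_curves <- function(model, loess_span = 0.3, grid_max = 75,
                               grid_step = 0.1) {
  stopifnot(inherits(model, "lape_forest"))
  grid <- seq(0, grid_max, by = grid_step)
  raw <- stats::predict(model$forest,
                        data = data.frame(score = grid))$predictions
  colnames(raw) <- as.character(1:3)
  smooth <- apply(raw, 2, function(p) {
    stats::predict(stats::loess(p ~ grid, span = loess_span,
                                degree = 2, family = "gaussian"))
  })
  structure(list(grid = grid, raw = raw, smooth = smooth,
                 loess_span = loess_span),
            class = "probability_curves")
}

# First (or last) score at which curve `hi` crosses strictly above `lo`,
# linearly interpolated between grid points; NA if no crossing.
curve_crossing <- function(grid, lo, hi, first = TRUE) {
  d <- hi - lo
  idx <- which(d[-1] > 0 & d[-length(d)] <= 0)
  if (!length(idx)) return(NA_real_)
  i <- if (first) idx[1] else idx[length(idx)]
  # interpolate the zero of d between grid[i] and grid[i+1]
  x0 <- grid[i]; x1 <- grid[i + 1]
  y0 <- d[i]; y1 <- d[i + 1]
  if (y1 == y0) return(x1)
  x0 - y0 * (x1 - x0) / (y1 - y0)
}

#' Extract category thresholds from probability curves
#'
#' The two LAPE cut points are placed where the smoothed class-probability
#' curves intersect: `t12` at the first score where the category-2 curve
#' rises above category 1's, `t23` at the last score where category 3's
#' rises above category 2's (keeping the three bands contiguous).
#'
#' @param curves a [probability_curves()] object.
#' @return A `lape_thresholds` list with `t12 < t23`.
#' @export
estimate_thresholds <- function(curves) {
  stopifnot(inherits(curves, "probability_curves"))
  g <- curves$grid; s <- curves$smooth
  t12 <- curve_crossing(g, s[, "1"], s[, "2"], first = TRUE)
  t23 <- curve_crossing(g, s[, "2"], s[, "3"], first = FALSE)
  if (is.na(t12) || is.na(t23))
    stop("probability curves do not intersect; training data are too ",
         "degenerate to place thresholds", call. = FALSE)
  if (!(t12 < t23))
    stop("extracted thresholds are not ordered (t12 >= t23)", call. = FALSE)
  lape_thresholds(t12, t23)
}

#' @rdname estimate_thresholds
#' @param t12,t23 cut points on the LAPE axis, `0 <= t12 < t23 <= 75`.
#' @export
lape_thresholds <- function(t12, t23) {
  if (!(t12 >= 0 && t12 < t23 && t23 <= 75))
    stop("need 0 <= t12 < t23 <= 75", call. = FALSE)
  structure(list(t12 = t12, t23 = t23), class = "lape_thresholds")
}

#' @export
print.lape_thresholds <- function(x, ...) {
  cat(sprintf(
    "LAPE thresholds: category 1 < %.1f; category 2 %.1f-%.1f; category 3 > %.1f\n",
    x$t12, x$t12, x$t23, x$t23))
  invisible(x)
}

#' Classify a LAPE score by fixed thresholds
#'
#' Category 1 below `t12`, category 3 above `t23`, category 2 between;
#' scores exactly at a threshold fall into the middle band (the outer
#' bands are strict).
#'
#' @param score numeric LAPE score(s).
#' @param thresholds a [lape_thresholds()] object.
#' @return Integer categories.
#' @export
#' @examples
#' classify_by_thresholds(c(5, 20, 40), lape_thresholds(8, 35))  # 1 2 3
classify_by_thresholds <- function(score, thresholds) {
  stopifnot(inherits(thresholds, "lape_thresholds"))
  ifelse(score < thresholds$t12, 1L,
         ifelse(score > thresholds$t23, 3L, 2L))
}

#' Simulate LAPE scores with planted category thresholds
#'
#' Draws class-conditional Gaussian scores (sd `sd`) whose
#' prior-weighted density crossings sit exactly at the planted
#' thresholds, so the population-optimal decision boundaries — what a
#' well-calibrated classifier should recover — are the thresholds
#' themselves.  The default 25%/50%/25% class mix mirrors the clinical
#' dominance of the middle grade.  Scores are clipped to the
#' working \[0, 75\] range.
#'
#' @param n number of scores.
#' @param thresholds planted [lape_thresholds()] (default the 8/35 band).
#' @param sd within-class standard deviation (default 3).
#' @param priors length-3 class proportions (default `c(0.25, 0.5, 0.25)`).
#' @param seed integer seed.
#' @return Data frame with `score` and `category`.
#' @export
simulate_lape_scores <- function(n, thresholds = lape_thresholds(8, 35),
                                 sd = 3, priors = c(0.25, 0.5, 0.25),
                                 seed = 1L) {
  stopifnot(inherits(thresholds, "lape_thresholds"))
  if (abs(sum(priors) - 1) > 1e-9 || any(priors < 0))
    stop("priors must be non-negative and sum to 1", call. = FALSE)
  means <- planted_class_means(thresholds, sd, priors)
  with_seed(seed, {
    category <- sample(1:3, n, replace = TRUE, prob = priors)
    score <- stats::rnorm(n, means[category], sd)
    data.frame(score = pmin(pmax(score, 0), 75), category = category)
  })
}

# Class means placing the prior-weighted Gaussian density crossings
# exactly at the thresholds.  The crossing of p_i N(m_i, sd) and
# p_j N(m_j, sd) lies at (m_i+m_j)/2 + sd^2 log(p_i/p_j)/(m_j-m_i);
# anchoring m1 = 0 (the darkest truncated patches) and solving the two
# resulting quadratics fixes m2 and m3.  For the (8, 35) band with
# sd = 3 and priors (.25, .5, .25): (0, 16.75, 52.91).
planted_class_means <- function(thresholds, sd = 3,
                                priors = c(0.25, 0.5, 0.25)) {
  t12 <- thresholds$t12; t23 <- thresholds$t23
  m1 <- 0
  disc12 <- t12^2 - 2 * sd^2 * log(priors[1] / priors[2])
  if (disc12 < 0)
    stop("no valid class-mean placement for these priors", call. = FALSE)
  m2 <- t12 + sqrt(disc12)
  disc23 <- (t23 - m2)^2 - 2 * sd^2 * log(priors[2] / priors[3])
  if (disc23 < 0 || t23 <= m2)
    stop("no valid class-mean placement for these priors", call. = FALSE)
  m3 <- t23 + sqrt(disc23)
  c(m1, m2, m3)
}
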