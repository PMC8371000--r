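check_categories <- function(x, arg = "labels") {
  x <- as.integer(x)
  if (any(is.na(x)) || !all(x %in% 1:3))
    stop(sprintf("`%s` must be categories in {1, 2, 3}", arg),
         call. = FALSE)
  x
}

#' Adjudicate one patch's grades
#'
#' Resolves the grades given to a single patch by several graders into one
#' reference-standard label: unanimity or majority wins; a full
#' disagreement (no majority) falls to the designated senior grader.  The
#' clinical reference standard resolved such splits by facilitated
#' discussion, which is not computable; the senior-grader rule is the
#' explicit stand-in, and `on_split = "flag"` returns `NA` instead so
#' those patches can be routed to manual review.
#'
#' @param grades integer vector of categories, one per grader.
#' @param graders character vector of grader ids (same length, no
#'   duplicates).
#' @param senior_grader id of the senior grader (must be among `graders`).
#' @param on_split `"senior"` (default) or `"flag"`.
#' @return The adjudicated category (or `NA` under `"flag"`).
#' @export
#' @examples
#' adjudicate(c(2, 3, 3), c("a", "b", "c"), senior_grader = "a")  # 3
adjudicate <- function(grades, graders, senior_grader,
                       on_split = c("senior", "flag")) {
  on_split <- match.arg(on_split)
  grades <- check_categories(grades, "grades")
  if (length(grades) < 2)
    stop("adjudication needs at least two graders", call. = FALSE)
  if (length(graders) != length(grades))
    stop("`graders` and `grades` lengths differ", call. = FALSE)
  if (anyDuplicated(graders))
    stop("duplicate grader for the same patch", call. = FALSE)
  if (!senior_grader %in% graders)
    stop("senior_grader must be among the graders", call. = FALSE)
  tab <- table(grades)
  top <- max(tab)
  if (top > length(grades) / 2)
    return(as.integer(names(tab)[which.max(tab)]))
  if (on_split == "flag") return(NA_integer_)
  grades[match(senior_grader, graders)]
}

#' Confusion matrix of predicted vs reference categories
#'
#' @param reference,predicted equal-length category vectors (values 1-3);
#'   rows of the result are the reference standard, columns the
#'   prediction.
#' @return A 3 x 3 integer matrix of counts, class `aoqc_confusion`.
#' @export
confusion <- function(reference, predicted) {
  reference <- check_categories(reference, "reference")
  predicted <- check_categories(predicted, "predicted")
  if (length(reference) != length(predicted))
    stop("reference and predicted lengths differ", call. = FALSE)
  cm <- table(factor(reference, levels = 1:3),
              factor(predicted, levels = 1:3))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(reference = 1:3, predicted = 1:3))
  structure(cm, class = c("aoqc_confusion", "matrix", "array"))
}

#' @export
print.aoqc_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = reference, cols = predicted)\n")
  print(unclass(x))
  cat(sprintf("accuracy: %.1f%%\n", accuracy(x)))
  invisible(x)
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm a confusion matrix (reference in rows, prediction in
#'   columns) with at least one observation.
#' @return Percentage of correctly classified patches (0-100).
#' @export
accuracy <- function(cm) {
  cm <- unclass(cm)
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm)) / sum(cm)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two raters on the same patches:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the product of the raters' marginal
#' distributions.  Unweighted; an optional linear weighting is available
#' for the ordinal scale but off by default.
#'
#' @param rater_a,rater_b equal-length category vectors.
#' @param weighting `"none"` (default) or `"linear"`.
#' @return Kappa in \[-1, 1\].
#' @export
#' @examples
#' cohens_kappa(c(1, 2, 3, 2), c(1, 2, 3, 2))  # 1
cohens_kappa <- function(rater_a, rater_b,
                         weighting = c("none", "linear")) {
  weighting <- match.arg(weighting)
  a <- check_categories(rater_a, "rater_a")
  b <- check_categories(rater_b, "rater_b")
  if (length(a) != length(b))
    stop("rater vectors must have equal length", call. = FALSE)
  if (!length(a)) stop("need at least one rating", call. = FALSE)
  tab <- table(factor(a, levels = 1:3), factor(b, levels = 1:3))
  p <- tab / sum(tab)
  w <- if (weighting == "none") diag(3) else 1 - abs(outer(1:3, 1:3, "-")) / 2
  po <- sum(w * p)
  pe <- sum(w * (rowSums(p) %o% colSums(p)))
  if (abs(1 - pe) < 1e-12) {
    if (abs(1 - po) < 1e-12) return(1)
    stop("kappa undefined: chance agreement is 1 with imperfect agreement",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Subject-wise train/validation split
#'
#' Splits a manifest into training and validation sets at the level of
#' subjects, never patches, so within-subject correlation cannot leak
#' across the split.  Both sides always receive at least one subject.
#'
#' @param manifest data frame with a `subject` column.
#' @param train_fraction fraction of subjects assigned to training, in
#'   (0, 1).
#' @param seed integer seed (deterministic split).
#' @return List with `train` and `validation` subject-id vectors and the
#'   corresponding row indices `train_idx`, `validation_idx`.
#' @export
subjectwise_split <- function(manifest, train_fraction = 23 / 50, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly in (0, 1)", call. = FALSE)
  subjects <- unique(manifest$subject)
  if (length(subjects) < 2)
    stop("need at least two subjects to split", call. = FALSE)
  n_train <- round(length(subjects) * train_fraction)
  n_train <- min(max(n_train, 1L), length(subjects) - 1L)
  train <- with_seed(seed, sample(subjects, n_train))
  validation <- setdiff(subjects, train)
  list(train = sort(train), validation = sort(validation),
       train_idx = which(manifest$subject %in% train),
       validation_idx = which(manifest$subject %in% validation))
}

#' Subject-stratified k-fold cross-validation
#'
#' Partitions subjects into `k` folds; each fold's patches are held out
#' once while a classifier is fitted on the rest, and the held-out
#' accuracy is recorded.
#'
#' @param manifest data frame with `subject` and `true_category` columns
#'   plus whatever the fitter needs (e.g. a `score` column).
#' @param k number of folds (default 10; must not exceed the number of
#'   subjects).
#' @param fit_fun `function(train_manifest)` returning a model.
#' @param predict_fun `function(model, test_manifest)` returning predicted
#'   categories.
#' @param seed integer seed for the fold assignment.
#' @return List with `fold_accuracy` (length `k`) and `mean_accuracy`.
#' @export
kfold_cv <- function(manifest, k = 10, fit_fun, predict_fun, seed = 1L) {
  subjects <- unique(manifest$subject)
  if (k > length(subjects))
    stop(sprintf("k = %d exceeds the %d available subjects", k,
                 length(subjects)), call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  fold_of <- with_seed(seed, {
    shuffled <- sample(subjects)
    stats::setNames(rep_len(seq_len(k), length(subjects)),
                    shuffled)
  })
  acc <- vapply(seq_len(k), function(f) {
    test_sub <- names(fold_of)[fold_of == f]
    test <- manifest[manifest$subject %in% test_sub, , drop = FALSE]
    train <- manifest[!manifest$subject %in% test_sub, , drop = FALSE]
    model <- fit_fun(train)
    pred <- predict_fun(model, test)
    accuracy(confusion(test$true_category, pred))
  }, numeric(1))
  list(fold_accuracy = acc, mean_accuracy = mean(acc))
}

#' Kruskal-Wallis test of focus scores across categories
#'
#' Rank-based comparison of LAPE scores between the three quality
#' categories (tie-corrected H statistic, chi-square approximation).
#'
#' @param scores numeric focus scores.
#' @param labels categories in 1-3 (same length).
#' @return List with `H`, `df` and `p_value`.
#' @export
kruskal_wallis_by_category <- function(scores, labels) {
  labels <- check_categories(labels)
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ", call. = FALSE)
  groups <- factor(labels)
  if (nlevels(droplevels(groups)) < 2)
    stop("need at least two non-empty categories", call. = FALSE)
  kt <- stats::kruskal.test(scores, droplevels(groups))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}
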