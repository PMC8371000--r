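#' Logistic regression of poor image quality on subject factors
#'
#' Fits the binary logistic model for poor image quality — category 2
#' ("poor", coded 1) versus category 3 ("analyzable", coded 0); truncated
#' category-1 patches carry no usable features and are excluded — on the
#' joint covariate set: healthy-vs-diseased status, retinal eccentricity
#' (degrees, pooled over meridians), age (years), axial length (mm),
#' spherical equivalent (D), visual acuity (ETDRS letters) and fixation
#' stability (BCEA63, deg^2).  Reports maximum-likelihood coefficients
#' with Wald 95% confidence intervals on the odds-ratio scale.
#'
#' Patches within a subject are treated as independent, mirroring the
#' plain (non-clustered) clinical analysis; `cluster_se = TRUE` switches
#' to cluster-robust (sandwich-by-subject) standard errors instead.
#'
#' @param manifest data frame with columns `true_category` (values in
#'   2:3 after filtering; category-1 rows and rows with missing
#'   covariates are dropped with a message), `group`
#'   (`"healthy"`/other), `eccentricity_deg`, `age`, `axial_length`,
#'   `spherical_equivalent`, `bcva`, `bcea63`, and `subject` when
#'   `cluster_se` is used.
#' @param cluster_se use cluster-robust standard errors by subject
#'   (default `FALSE`).
#' @return A `quality_factor_fit`: data frame `report` (term, estimate,
#'   se, odds_ratio, ci_low, ci_high) plus the underlying `glm` fit.
#' @export
fit_quality_logistic <- function(manifest, cluster_se = FALSE) {
  need <- c("true_category", "group", "eccentricity_deg", "age",
            "axial_length", "spherical_equivalent", "bcva", "bcea63")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dat <- manifest[manifest$true_category %in% c(2L, 3L), need,
                  drop = FALSE]
  n_cat1 <- sum(manifest$true_category == 1L)
  keep <- stats::complete.cases(dat)
  if (any(!keep))
    message(sum(!keep), " rows with missing covariates dropped")
  dat <- dat[keep, , drop = FALSE]
  if (n_cat1 > 0)
    message(n_cat1, " category-1 (truncated) patches excluded from the ",
            "factor analysis")
  if (!all(c(2L, 3L) %in% dat$true_category))
    stop("both outcome classes (categories 2 and 3) must be present",
         call. = FALSE)
  dat$poor <- as.integer(dat$true_category == 2L)
  dat$diseased <- as.integer(dat$group != "healthy")

  fit <- stats::glm(
    poor ~ diseased + eccentricity_deg + age + axial_length +
      spherical_equivalent + bcva + bcea63,
    family = stats::binomial(), data = dat)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design: covariate(s) ",
         paste(aliased, collapse = ", "), " are aliased (too few ",
         "subjects for the covariate set)", call. = FALSE)
  }
  if (!fit$converged || any(abs(stats::coef(fit)) > 15)) {
    worst <- names(which.max(abs(stats::coef(fit))[-1]))
    stop("logistic fit did not converge (possible separation on `",
         worst, "`)", call. = FALSE)
  }

  est <- stats::coef(fit)
  if (cluster_se) {
    if (!"subject" %in% names(manifest))
      stop("cluster_se = TRUE needs a `subject` column", call. = FALSE)
    se <- cluster_robust_se(fit,
                            manifest$subject[manifest$true_category %in%
                                               c(2L, 3L)][keep])
  } else {
    se <- summary(fit)$coefficients[, "Std. Error"]
  }
  report <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    odds_ratio = exp(unname(est)),
    ci_low = exp(unname(est) - 1.96 * unname(se)),
    ci_high = exp(unname(est) + 1.96 * unname(se)),
    row.names = NULL)
  structure(list(report = report, fit = fit, n = nrow(dat),
                 cluster_se = cluster_se),
            class = "quality_factor_fit")
}

# Sandwich estimator with CR0 clustering by subject.
cluster_robust_se <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  r <- stats::residuals(fit, type = "response")
  scores <- X * r
  G <- rowsum(scores, cluster)
  bread <- stats::vcov(fit)
  V <- bread %*% crossprod(G) %*% bread
  sqrt(diag(V))
}

#' @export
print.quality_factor_fit <- function(x, ...) {
  cat(sprintf("Poor-quality (category 2 vs 3) logistic model, n = %d%s\n",
              x$n, if (x$cluster_se) " (cluster-robust SE)" else ""))
  r <- x$report
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-22s OR %6.3f  (95%% CI %6.3f - %6.3f)\n",
                r$term[i], r$odds_ratio[i], r$ci_low[i], r$ci_high[i]))
  invisible(x)
}

#' Frequency of poor-quality patches by retinal location
#'
#' For each eccentricity and study group, the fraction of patches graded
#' category 2 among the analyzable set (categories 2 and 3; truncated
#' category-1 patches are filtered out first).  Loci beyond 10 degrees
#' are excluded.
#'
#' @param manifest data frame with `true_category`, `eccentricity_deg`
#'   and `group` columns.
#' @return Data frame `(eccentricity_deg, group, n, fraction_category2)`;
#'   empty cells are absent.
#' @export
category_frequency_by_location <- function(manifest) {
  d <- manifest[manifest$true_category %in% c(2L, 3L) &
                  manifest$eccentricity_deg <= 10, , drop = FALSE]
  if (!nrow(d))
    return(data.frame(eccentricity_deg = numeric(0), group = character(0),
                      n = integer(0), fraction_category2 = numeric(0)))
  agg <- stats::aggregate(
    cbind(n = rep(1L, nrow(d)), poor = as.integer(d$true_category == 2L)),
    by = list(eccentricity_deg = d$eccentricity_deg, group = d$group),
    FUN = sum)
  data.frame(eccentricity_deg = agg$eccentricity_deg, group = agg$group,
             n = agg$n, fraction_category2 = agg$poor / agg$n)
}

#' Per-subject poor-quality burden
#'
#' For each subject, the fraction of category-2 patches among that
#' subject's analyzable patches (categories 2 and 3), and the cohort-level
#' share of subjects for whom half or more of their analyzable patches are
#' poor (fraction >= 0.5, boundary inclusive).  Subjects with no
#' analyzable patches are excluded with a warning.
#'
#' @param manifest data frame with `subject` and `true_category` columns.
#' @return List: `per_subject` data frame
#'   `(subject, n, fraction_category2)` and `share_half_or_more`.
#' @export
subject_fraction_poor <- function(manifest) {
  d <- manifest[manifest$true_category %in% c(2L, 3L), , drop = FALSE]
  all_subjects <- unique(manifest$subject)
  dropped <- setdiff(all_subjects, unique(d$subject))
  if (length(dropped))
    warning(length(dropped), " subject(s) with no analyzable patches ",
            "excluded: ", paste(dropped, collapse = ", "), call. = FALSE)
  agg <- stats::aggregate(
    cbind(n = rep(1L, nrow(d)), poor = as.integer(d$true_category == 2L)),
    by = list(subject = d$subject), FUN = sum)
  per_subject <- data.frame(subject = agg$subject, n = agg$n,
                            fraction_category2 = agg$poor / agg$n)
  list(per_subject = per_subject,
       share_half_or_more = mean(per_subject$fraction_category2 >= 0.5))
}
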