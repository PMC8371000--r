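#' Planted covariate model for patch quality
#'
#' Odds ratios governing the probability that an untruncated patch is poor
#' quality (category 2 rather than 3) in the synthetic cohort.  Defaults
#' are the effect sizes observed clinically: diseased eyes 5.2 times more
#' likely to yield a poor patch, and each degree of eccentricity and each
#' year of age multiplying the odds by 1.03; the remaining biometric
#' covariates are null.
#'
#' @param disease_or odds ratio of diseased vs healthy.
#' @param eccentricity_or odds ratio per degree of eccentricity.
#' @param age_or odds ratio per year of age.
#' @param axial_length_or,spherical_equivalent_or,bcva_or,bcea63_or odds
#'   ratios per unit of the remaining covariates (default 1 = no effect).
#' @return A `quality_factor_model` list of log odds ratios.
#' @export
quality_factor_model <- function(disease_or = 5.2, eccentricity_or = 1.03,
                                 age_or = 1.03, axial_length_or = 1,
                                 spherical_equivalent_or = 1, bcva_or = 1,
                                 bcea63_or = 1) {
  ors <- c(disease = disease_or, eccentricity = eccentricity_or,
           age = age_or, axial_length = axial_length_or,
           spherical_equivalent = spherical_equivalent_or,
           bcva = bcva_or, bcea63 = bcea63_or)
  if (any(ors <= 0)) stop("odds ratios must be positive", call. = FALSE)
  structure(list(log_or = log(ors)), class = "quality_factor_model")
}

# Reference (centering) values for the covariates, so the calibrated
# intercept refers to an average patch.
covariate_centers <- c(age = 57, axial_length = 23.7,
                       spherical_equivalent = 0, bcva = 88, bcea63 = 1.5,
                       eccentricity = 5.5)

# Draw per-subject biometry emulating the three clinical study groups
# (healthy / macular-surgery distortion (DSM) / hydroxychloroquine (HCQ)).
draw_subjects <- function(n_subjects) {
  grp <- sample(c("healthy", "DSM", "HCQ"), n_subjects, replace = TRUE,
                prob = c(28, 11, 11) / 50)
  par <- list(
    healthy = list(age = c(55, 17), al = c(24.0, 0.9), va = c(90.1, 4.8),
                   se = c(0.0, 1.8), bcea = c(1.1, 1.3)),
    DSM     = list(age = c(62, 18), al = c(23.3, 1.0), va = c(82.8, 8.3),
                   se = c(-0.5, 1.1), bcea = c(1.2, 1.3)),
    HCQ     = list(age = c(59, 7), al = c(23.1, 0.8), va = c(87.2, 4.9),
                   se = c(0.9, 1.8), bcea = c(2.9, 4.2)))
  g <- function(field, i) par[[grp[i]]][[field]]
  draw <- function(field, lo, hi) {
    vapply(seq_len(n_subjects), function(i) {
      m <- g(field, i)
      min(max(stats::rnorm(1, m[1], m[2]), lo), hi)
    }, numeric(1))
  }
  data.frame(subject = sprintf("S%03d", seq_len(n_subjects)),
             group = grp,
             age = draw("age", 20, 95),
             axial_length = draw("al", 21, 27),
             bcva = draw("va", 40, 100),
             spherical_equivalent = draw("se", -6, 4),
             bcea63 = pmax(draw("bcea", 0.05, 15), 0.05),
             stringsAsFactors = FALSE)
}

# Linear predictor of "poor" (category 2) for eligible patches, without
# the intercept; covariates centered at covariate_centers.
quality_linear_predictor <- function(meta, model) {
  b <- model$log_or
  diseased <- as.numeric(meta$group != "healthy")
  b[["disease"]] * diseased +
    b[["eccentricity"]] * (meta$eccentricity_deg -
                             covariate_centers[["eccentricity"]]) +
    b[["age"]] * (meta$age - covariate_centers[["age"]]) +
    b[["axial_length"]] * (meta$axial_length -
                             covariate_centers[["axial_length"]]) +
    b[["spherical_equivalent"]] *
      (meta$spherical_equivalent -
         covariate_centers[["spherical_equivalent"]]) +
    b[["bcva"]] * (meta$bcva - covariate_centers[["bcva"]]) +
    b[["bcea63"]] * (meta$bcea63 - covariate_centers[["bcea63"]])
}

# Scene parameters consistent with a target category at one retinal locus.
# Blur/noise ranges for categories 2 and 3 deliberately overlap, mirroring
# the considerable overlap of focus scores between those grades.
draw_scene_params <- function(category, eccentricity_deg, pixel_scale,
                              seed) {
  spacing <- max(2.2, 2.8 + 0.5 * eccentricity_deg + stats::rnorm(1, 0, 0.3))
  cv <- stats::runif(1, 0.2, 0.45)
  # noise is mild throughout: each acquisition averages 40 registered
  # frames.  Mosaic edges (category 1) are also defocused — edge-of-field
  # optics — and categories 2/3 have overlapping blur ranges, mirroring
  # the considerable overlap of focus scores between those grades.
  if (category == 1L) {
    tf <- stats::runif(1, 0.08, 0.40)
    quads <- character(0)
    psf <- stats::runif(1, 1.5, 3.5)
    noise <- stats::runif(1, 0.005, 0.02)
  } else if (category == 2L) {
    tf <- stats::runif(1, 0, 0.04)
    if (stats::runif(1) < 0.8) {
      quads <- sample(c("TL", "TR", "BL", "BR"),
                      sample(1:4, 1, prob = c(0.45, 0.3, 0.15, 0.1)))
      psf <- stats::runif(1, 1.0, 2.5)
    } else {
      quads <- character(0)
      psf <- stats::runif(1, 2.6, 4.0)
    }
    noise <- stats::runif(1, 0.01, 0.03)
  } else {
    tf <- 0
    quads <- character(0)
    psf <- stats::runif(1, 0.2, 0.9)
    noise <- stats::runif(1, 0.005, 0.02)
  }
  scene_params(cone_spacing = spacing, reflex_cv = cv, psf_sigma = psf,
               noise_sigma = noise, truncation_fraction = tf,
               degraded_quadrants = quads, pixel_scale = pixel_scale,
               seed = seed)
}

#' Simulate a graded AO-FIO cohort
#'
#' Generates a cohort of subjects with realistic biometry and, for each
#' subject, one 50 um sampling window at every locus of the standard ROI
#' grid (eccentricities 1-10 degrees on four meridians).  Truncated
#' (category 1) patches occur at the marginal rate `category_mix[1]`
#' independently of covariates — truncation is a mosaic-geometry artifact
#' — while the category 2 vs 3 outcome of the remaining patches follows
#' the planted logistic model in the covariates, with the intercept
#' calibrated so the overall mix matches `category_mix`.  Every patch's
#' ground-truth label equals `plant_category()` of its scene parameters.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param category_mix length-3 vector of target category proportions
#'   (default the clinically observed 20/56/24 split); must sum to 1.
#' @param covariate_model a [quality_factor_model()].
#' @param seed integer master seed; the full cohort is reproducible.
#' @param render if `FALSE`, skip image rendering and return metadata only
#'   (categories, covariates, scene parameters) — sufficient for
#'   factor-model studies and orders of magnitude faster.
#' @param patches_per_subject optional cap; by default all 40 grid loci.
#' @return An `aoqc_cohort` list: `manifest` (one row per patch) and
#'   `patches` (list of [ao_patch], `NULL` when `render = FALSE`).
#' @export
generate_cohort <- function(n_subjects, category_mix = c(0.20, 0.56, 0.24),
                            covariate_model = quality_factor_model(),
                            seed = 1L, render = TRUE,
                            patches_per_subject = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (length(category_mix) != 3 || any(category_mix < 0) ||
      abs(sum(category_mix) - 1) > 1e-9)
    stop("category_mix must be 3 non-negative proportions summing to 1",
         call. = FALSE)
  stopifnot(inherits(covariate_model, "quality_factor_model"))

  cohort <- with_seed(seed, {
    subjects <- draw_subjects(n_subjects)
    grid <- roi_grid()
    grid <- grid[grid$eccentricity_deg > 0, ]   # fovea not sampled
    if (!is.null(patches_per_subject))
      grid <- grid[seq_len(min(patches_per_subject, nrow(grid))), ]
    meta <- merge(subjects, grid, by = NULL)    # cross join
    meta <- meta[order(meta$subject, meta$meridian, meta$eccentricity_deg), ]
    rownames(meta) <- NULL
    n <- nrow(meta)

    # category 1 hits are covariate-independent
    is_cat1 <- stats::runif(n) < category_mix[1]
    eta <- quality_linear_predictor(meta, covariate_model)
    p2_target <- if (sum(category_mix[2:3]) > 0)
      category_mix[2] / sum(category_mix[2:3]) else 0
    if (p2_target <= 0) {
      p2 <- rep(0, n)
    } else if (p2_target >= 1) {
      p2 <- rep(1, n)
    } else {
      alpha <- stats::uniroot(function(a)
        mean(stats::plogis(a + eta)) - p2_target, c(-30, 30))$root
      p2 <- stats::plogis(alpha + eta)
    }
    category <- ifelse(is_cat1, 1L,
                       ifelse(stats::runif(n) < p2, 2L, 3L))

    q_ref <- magnification_factor(24.0)
    px_scale <- (50 / 65) * magnification_factor(meta$axial_length) / q_ref
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    params <- lapply(seq_len(n), function(i)
      draw_scene_params(category[i], meta$eccentricity_deg[i],
                        px_scale[i], seeds[i]))
    true_cat <- vapply(params, plant_category, integer(1))
    stopifnot(identical(true_cat, as.integer(category)))

    manifest <- cbind(
      patch_id = sprintf("P%05d", seq_len(n)),
      meta,
      window = "Mid",
      true_category = true_cat,
      data.frame(
        cone_spacing = vapply(params, `[[`, numeric(1), "cone_spacing"),
        reflex_cv = vapply(params, `[[`, numeric(1), "reflex_cv"),
        psf_sigma = vapply(params, `[[`, numeric(1), "psf_sigma"),
        noise_sigma = vapply(params, `[[`, numeric(1), "noise_sigma"),
        truncation_fraction = vapply(params, `[[`, numeric(1),
                                     "truncation_fraction"),
        degraded_quadrants = vapply(params, function(p)
          paste(p$degraded_quadrants, collapse = "+"), character(1)),
        pixel_scale = vapply(params, `[[`, numeric(1), "pixel_scale"),
        scene_seed = vapply(params, `[[`, integer(1), "seed")))
    list(manifest = manifest, params = params)
  })

  patches <- NULL
  if (render) {
    patches <- lapply(seq_along(cohort$params), function(i) {
      lp <- generate_patch(cohort$params[[i]])
      attr(lp$patch, "provenance") <- list(
        subject = cohort$manifest$subject[i],
        eccentricity_deg = cohort$manifest$eccentricity_deg[i],
        meridian = cohort$manifest$meridian[i],
        window = "Mid")
      lp$patch
    })
    names(patches) <- cohort$manifest$patch_id
  }
  structure(list(manifest = cohort$manifest, patches = patches,
                 params = cohort$params, seed = as.integer(seed)),
            class = "aoqc_cohort")
}

#' @export
print.aoqc_cohort <- function(x, ...) {
  tab <- table(factor(x$manifest$true_category, levels = 1:3))
  cat(sprintf(
    "<aoqc_cohort> %d patches from %d subjects (%srendered)\n",
    nrow(x$manifest), length(unique(x$manifest$subject)),
    if (is.null(x$patches)) "not " else ""))
  cat(sprintf("  categories 1/2/3: %d/%d/%d\n", tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Saves each rendered patch as a 16-bit grayscale TIFF plus a sidecar CSV
#' manifest with the ground-truth category, scene parameters and subject
#' covariates.
#'
#' @param cohort an `aoqc_cohort` with rendered patches.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "aoqc_cohort"))
  if (is.null(cohort$patches))
    stop("cohort has no rendered patches (render = FALSE)", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(cohort$patches), function(i) {
    f <- file.path(dir, paste0(cohort$manifest$patch_id[i], ".tif"))
    tiff::writeTIFF(unclass(cohort$patches[[i]]), f, bits.per.sample = 16L)
    f
  }, character(1))
  man <- cohort$manifest
  man$patch_path <- paths
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}

#' Read patches listed in a manifest
#'
#' @param manifest_path path to a `manifest.csv` written by
#'   [write_cohort()] (or with at least `patch_path` and `pixel_scale`
#'   columns).
#' @return An `aoqc_cohort` with patches loaded from TIFF.
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!"patch_path" %in% names(man))
    stop("manifest lacks a patch_path column", call. = FALSE)
  patches <- lapply(seq_len(nrow(man)), function(i) {
    img <- tiff::readTIFF(man$patch_path[i])
    ps <- if ("pixel_scale" %in% names(man)) man$pixel_scale[i] else 50 / 65
    ao_patch(img, pixel_scale = ps)
  })
  names(patches) <- man$patch_id
  structure(list(manifest = man, patches = patches, params = NULL,
                 seed = NA_integer_), class = "aoqc_cohort")
}
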