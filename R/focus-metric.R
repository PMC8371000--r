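#' Brightness normalization
#'
#' Multiplicatively rescales a patch so its mean intensity equals a fixed
#' reference level.  This is the "normalized for brightness" conditioning
#' step applied before the Laplacian focus operator; because the rescale is
#' purely multiplicative it makes the LAPE score invariant to global
#' illumination changes.
#'
#' @param patch an [ao_patch] or numeric matrix with positive mean.
#' @param target reference mean intensity on a \[0, 1\] scale (default 0.5).
#' @return The rescaled patch (same class and metadata).
#' @export
#' @examples
#' normalize_brightness(ao_patch(matrix(0.25, 5, 5)))[1, 1]  # 0.5
normalize_brightness <- function(patch, target = 0.5) {
  p <- as_patch(patch)
  x <- unclass(p)
  imaged <- x > 0            # exact zeros are outside the mosaic
  if (!any(imaged))
    stop("degenerate patch: no imaged pixels; ",
         "an all-blank window should be classified as truncated, not scored",
         call. = FALSE)
  m <- mean(x[imaged])       # reference mean over imaged pixels only, so
  rewrap_patch(x * (target / m), p)   # truncation cannot inflate the rest
}

# Discrete Laplacian response on interior pixels (no padding).
# Returns an (n-2) x (m-2) matrix of filter responses.
laplacian_interior <- function(x, kernel = c("lap4", "lap8")) {
  kernel <- match.arg(kernel)
  n <- nrow(x); m <- ncol(x)
  ic <- 2:(n - 1L); jc <- 2:(m - 1L)
  up    <- x[ic - 1L, jc, drop = FALSE]
  down  <- x[ic + 1L, jc, drop = FALSE]
  left  <- x[ic, jc - 1L, drop = FALSE]
  right <- x[ic, jc + 1L, drop = FALSE]
  ctr   <- x[ic, jc, drop = FALSE]
  if (kernel == "lap4") {
    up + down + left + right - 4 * ctr
  } else {
    diag1 <- x[ic - 1L, jc - 1L, drop = FALSE]
    diag2 <- x[ic - 1L, jc + 1L, drop = FALSE]
    diag3 <- x[ic + 1L, jc - 1L, drop = FALSE]
    diag4 <- x[ic + 1L, jc + 1L, drop = FALSE]
    up + down + left + right + diag1 + diag2 + diag3 + diag4 - 8 * ctr
  }
}

#' Energy-of-Laplacian (LAPE) focus score
#'
#' The LAPE no-reference focus measure: the patch is normalized for
#' brightness, convolved with a discrete Laplacian kernel, and the energy
#' (sum of squared responses) is accumulated over interior pixels only, so
#' no border response is fabricated.  The mean energy per interior pixel is
#' scaled by a single calibration constant chosen so that sharp,
#' fully-resolved cone-mosaic patches score in the upper part of the
#' instrument's working 0-75 range; defocused or structureless patches
#' score near 0.
#'
#' The score is invariant to multiplying the input by any positive
#' constant (a consequence of the brightness normalization) and is exactly
#' 0 for a constant patch.
#'
#' @param patch an [ao_patch] or numeric matrix (>= 3 x 3, non-negative).
#' @param kernel `"lap4"` for the 5-point Laplacian
#'   `[[0,1,0],[1,-4,1],[0,1,0]]` (the canonical LAPE kernel) or `"lap8"`
#'   for the 8-neighbour variant.
#' @param calibration multiplier applied to the mean per-pixel energy;
#'   defaults to [lape_calibration()].
#' @return A single non-negative numeric score.
#' @seealso [lape_blur_profile()], [classify_by_thresholds()]
#' @export
#' @examples
#' lape(matrix(1, 9, 9))  # constant patch -> 0
lape <- function(patch, kernel = c("lap4", "lap8"),
                 calibration = lape_calibration()) {
  kernel <- match.arg(kernel)
  p <- normalize_brightness(patch)
  L <- laplacian_interior(unclass(p), kernel)
  sum(L^2) / length(L) * calibration
}

#' @rdname lape
#' @details `lape_calibration()` returns the package-level calibration
#'   constant (settable via `options(aoqc.lape_calibration = ...)`).
#' @export
lape_calibration <- function() {
  getOption("aoqc.lape_calibration", 750)
}

#' LAPE as a function of defocus
#'
#' Scores a patch after Gaussian defocus blur at each of a set of blur
#' widths, in order.  Useful as a diagnostic: on cone-mosaic patches the
#' score decreases monotonically as defocus grows.
#'
#' @param patch an [ao_patch] or numeric matrix.
#' @param sigmas non-decreasing, non-negative blur standard deviations in
#'   micrometres (converted to pixels via the patch's pixel scale).
#' @inheritParams lape
#' @return Numeric vector of LAPE scores, one per sigma.
#' @export
lape_blur_profile <- function(patch, sigmas, kernel = c("lap4", "lap8"),
                              calibration = lape_calibration()) {
  kernel <- match.arg(kernel)
  if (any(sigmas < 0)) stop("blur sigmas must be non-negative", call. = FALSE)
  if (is.unsorted(sigmas)) stop("blur sigmas must be increasing", call. = FALSE)
  p <- as_patch(patch)
  vapply(sigmas, function(s) {
    lape(blur_patch(p, s), kernel = kernel, calibration = calibration)
  }, numeric(1))
}

#' Gaussian defocus blur of a patch
#'
#' Applies an isotropic Gaussian blur of standard deviation `sigma_um`
#' micrometres (converted to pixels through the patch's pixel scale).
#' `sigma_um = 0` returns the patch unchanged.
#'
#' @inheritParams lape
#' @param sigma_um blur standard deviation in micrometres (>= 0).
#' @return The blurred patch.
#' @export
blur_patch <- function(patch, sigma_um) {
  p <- as_patch(patch)
  if (sigma_um < 0) stop("sigma_um must be non-negative", call. = FALSE)
  if (sigma_um == 0) return(p)
  sigma_px <- sigma_um / pixel_scale(p)
  blurred <- EBImage::gblur(unclass(p), sigma = sigma_px,
                            boundary = "replicate")
  rewrap_patch(as.matrix(blurred), p)
}
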