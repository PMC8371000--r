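#' Axial-length magnification factor
#'
#' Converts an eye's axial length to the retinal magnification factor `q`
#' (millimetres of retina per degree of visual angle) with Bennett's
#' adjusted Littmann method: `q = 0.013063 * (AL - 1.82)`.
#'
#' @param axial_length axial length in millimetres; must exceed 1.82 mm,
#'   the formula's zero point.
#' @return Magnification factor in mm per degree.
#' @export
#' @examples
#' magnification_factor(24.0)  # 0.28974 mm/deg
magnification_factor <- function(axial_length) {
  if (any(!is.finite(axial_length)) || any(axial_length < 1.82))
    stop("axial_length must be > 1.82 mm (formula domain)", call. = FALSE)
  0.013063 * (axial_length - 1.82)
}

#' Visual angle to retinal distance
#'
#' Converts an eccentricity in degrees of visual field to micrometres on
#' the retina for a given eye: `q(AL) * angle * 1000`.
#'
#' @param angle_deg angle in degrees (>= 0); vectorised.
#' @param axial_length axial length in mm (> 1.82).
#' @return Retinal distance in micrometres.
#' @export
#' @examples
#' degrees_to_micrometers(1, 24.0)  # 289.74 um
degrees_to_micrometers <- function(angle_deg, axial_length) {
  if (any(angle_deg < 0)) stop("angle must be non-negative", call. = FALSE)
  magnification_factor(axial_length) * angle_deg * 1000
}

#' Standard ROI grid
#'
#' The standard sampling grid for one eye: the foveal centre plus integer
#' eccentricities 1-10 degrees along the four principal meridians — 41
#' retinal loci in total.
#'
#' @return A data frame with columns `eccentricity_deg` and `meridian`.
#' @export
roi_grid <- function() {
  merid <- c("superior", "inferior", "nasal", "temporal")
  rbind(data.frame(eccentricity_deg = 0, meridian = "fovea"),
        expand.grid(eccentricity_deg = 1:10, meridian = merid,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
}

#' Extract the five overlapping sampling windows
#'
#' Cuts the five standard sampling windows (`Mid`, `TL`, `TR`, `BL`, `BR`)
#' out of a region-of-interest image.  `Mid` is centred on the ROI centre;
#' the four corner windows are displaced diagonally by `offset_um` in each
#' axis and partially overlap `Mid`.  Every window is an exact sub-view of
#' the input (pixel identity preserved).
#'
#' @param roi_image an [ao_patch] or matrix covering the ROI.
#' @param window_um window side in micrometres (default 50, i.e. 65 px at
#'   the default pixel scale).
#' @param offset_um diagonal displacement of the corner windows in
#'   micrometres; the default 25 um (half a window) leaves each corner
#'   window overlapping `Mid` on 25% of its area.
#' @return Named list of five `ao_patch` windows tagged
#'   `Mid`, `TL`, `TR`, `BL`, `BR`.
#' @export
extract_windows <- function(roi_image, window_um = 50, offset_um = 25) {
  p <- as_patch(roi_image)
  ps <- pixel_scale(p)
  side <- as.integer(round(window_um / ps))
  off <- as.integer(round(offset_um / ps))
  n <- nrow(p); m <- ncol(p)
  cr <- floor(n / 2) + 1L; cc <- floor(m / 2) + 1L   # ROI centre pixel
  half_lo <- floor((side - 1L) / 2)

  win_at <- function(r0, c0, tag) {
    rows <- (r0 - half_lo):(r0 - half_lo + side - 1L)
    cols <- (c0 - half_lo):(c0 - half_lo + side - 1L)
    if (rows[1] < 1L || cols[1] < 1L || rows[side] > n || cols[side] > m)
      stop(sprintf(paste0("ROI too small for window '%s': need rows %d..%d,",
                          " cols %d..%d but image is %d x %d px"),
                   tag, rows[1], rows[side], cols[1], cols[side], n, m),
           call. = FALSE)
    prov <- c(attr(p, "provenance"), list(window = tag))
    structure(unclass(p)[rows, cols, drop = FALSE],
              pixel_scale = ps, provenance = prov,
              class = c("ao_patch", "matrix", "array"))
  }

  list(Mid = win_at(cr, cc, "Mid"),
       TL  = win_at(cr - off, cc - off, "TL"),
       TR  = win_at(cr - off, cc + off, "TR"),
       BL  = win_at(cr + off, cc - off, "BL"),
       BR  = win_at(cr + off, cc + off, "BR"))
}

#' Fraction of a patch outside the imaged mosaic
#'
#' Mosaic compositors write exact zeros outside the imaged area, so blank
#' (truncated) pixels are detected as intensities at or below
#' `blank_threshold`.
#'
#' @param patch an [ao_patch] or matrix.
#' @param blank_threshold intensities `<=` this value count as blank
#'   (default 0; raise for formats with a noise floor).
#' @return Fraction of blank pixels, in \[0, 1\].
#' @export
truncation_fraction <- function(patch, blank_threshold = 0) {
  x <- unclass(as_patch(patch))
  mean(x <= blank_threshold)
}

#' Automated category-1 rule
#'
#' A patch is category 1 (mosaic edge, unusable) when strictly more than
#' 5% of its area is truncated.  Exactly 5% is not category 1.
#'
#' @inheritParams truncation_fraction
#' @param threshold truncated-area fraction above which the patch is
#'   category 1 (default 0.05).
#' @return Logical.
#' @export
auto_category1 <- function(patch, threshold = 0.05, blank_threshold = 0) {
  truncation_fraction(patch, blank_threshold) > threshold
}
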