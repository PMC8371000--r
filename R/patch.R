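#' AO image patch
#'
#' A lightweight container for one grayscale sampling window: a numeric
#' matrix of intensities plus the physical pixel scale and optional
#' provenance (subject, eccentricity, meridian, window tag).
#'
#' Intensities are stored row-major with the top-left pixel at `[1, 1]`;
#' they must be finite and non-negative.  The default pixel scale of
#' 50/65 um/px makes a 50 um sampling window exactly 65 px wide, the
#' native patch size of this toolkit.
#'
#' @param intensities numeric matrix, at least 3 x 3, finite, >= 0.
#' @param pixel_scale micrometres per pixel (> 0).
#' @param provenance optional named list (e.g. subject, eccentricity_deg,
#'   meridian, window).
#' @return An object of class `ao_patch`.
#' @export
#' @examples
#' p <- ao_patch(matrix(runif(25), 5, 5))
#' dim(p)
ao_patch <- function(intensities, pixel_scale = 50 / 65, provenance = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  if (nrow(intensities) < 3L || ncol(intensities) < 3L)
    stop("patch must be at least 3 x 3 px (Laplacian kernel support)",
         call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("patch intensities must be finite", call. = FALSE)
  if (any(intensities < 0))
    stop("patch intensities must be non-negative", call. = FALSE)
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1L || pixel_scale <= 0)
    stop("`pixel_scale` must be a single positive number (um/px)",
         call. = FALSE)
  structure(intensities,
            pixel_scale = as.numeric(pixel_scale),
            provenance = provenance,
            class = c("ao_patch", "matrix", "array"))
}

#' @export
print.ao_patch <- function(x, ...) {
  cat(sprintf("<ao_patch> %d x %d px, %.4f um/px, range [%.3g, %.3g]\n",
              nrow(x), ncol(x), attr(x, "pixel_scale"), min(x), max(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov))
    cat("  provenance:", paste(names(prov), unlist(prov), sep = "=",
                               collapse = ", "), "\n")
  invisible(x)
}

# Coerce to ao_patch, preserving an existing patch's metadata.
as_patch <- function(x, pixel_scale = 50 / 65) {
  if (inherits(x, "ao_patch")) return(x)
  ao_patch(x, pixel_scale = pixel_scale)
}

#' @export
#' @rdname ao_patch
#' @param x an `ao_patch`.
pixel_scale <- function(x) {
  ps <- attr(x, "pixel_scale")
  if (is.null(ps)) 50 / 65 else ps
}

# Rebuild a patch around new intensities, keeping metadata.
rewrap_patch <- function(values, template) {
  structure(values,
            pixel_scale = pixel_scale(template),
            provenance = attr(template, "provenance"),
            class = c("ao_patch", "matrix", "array"))
}
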