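#' Concentric sampling ring specification
#'
#' Geometry of one ring of square ROIs: ROI centers lie on a circle of
#' radius `radius_px` around `center_px`, separated by an arc length of
#' `spacing_px` pixels on the circumference. The defaults (16 x 16 px ROIs,
#' 8 px spacing) give ~50% tangential overlap between neighbouring ROIs,
#' which trades patch independence for denser angular sampling.
#'
#' @param center_px ring center `c(row, col)` in pixels (1-based, may be
#'   fractional).
#' @param radius_px circle radius in pixels.
#' @param roi_size ROI side length in pixels; scalar or `c(rows, cols)`,
#'   each at least 2.
#' @param spacing_px center-to-center arc distance between adjacent ROIs.
#' @return an object of class `ring_spec`.
#' @export
ring_spec <- function(center_px, radius_px, roi_size = 16L, spacing_px = 8) {
  if (length(center_px) != 2 || any(!is.finite(center_px))) {
    stop("center_px must be a finite (row, col) pair")
  }
  if (!is.finite(radius_px) || radius_px <= 0) {
    stop("radius_px must be positive")
  }
  roi_size <- as.integer(roi_size)
  if (length(roi_size) == 1) roi_size <- c(roi_size, roi_size)
  if (any(roi_size < 2)) stop("roi_size must be at least 2 pixels")
  if (!is.finite(spacing_px) || spacing_px <= 0) {
    stop("spacing_px must be positive")
  }
  structure(list(center_px = as.numeric(center_px),
                 radius_px = as.numeric(radius_px),
                 roi_size = roi_size, spacing_px = as.numeric(spacing_px)),
            class = "ring_spec")
}

# 1-based index range of an n-wide patch around an integer center.
# Even n follows the half-open convention [center - n/2, center + n/2) in
# 0-based coordinates, i.e. (c - n/2):(c + n/2 - 1) once 1-based; odd n is
# symmetric about the center.
patch_range <- function(center, n) {
  if (n %% 2 == 0) (center - n %/% 2):(center + n %/% 2 - 1L)
  else (center - n %/% 2):(center + n %/% 2)
}

#' ROI centers along a sampling ring
#'
#' Places ROI centers at equal angular steps `theta = spacing_px /
#' radius_px` starting at angle 0 (the 3 o'clock direction; angles advance
#' toward increasing rows), rounded to the nearest integer pixel. The count
#' is `floor(2 * pi * radius / spacing)`.
#'
#' @param ring a [ring_spec()].
#' @param image_shape image dimensions `c(rows, cols)`.
#' @param on_oob what to do when a full ROI around a center does not fit in
#'   the image: `"error"` (default) or `"drop"` (used when a mask filter
#'   will be applied downstream).
#' @return integer matrix with columns `row`, `col`, one center per row,
#'   in angular order.
#' @export
ring_roi_centers <- function(ring, image_shape, on_oob = c("error", "drop")) {
  stopifnot(inherits(ring, "ring_spec"))
  on_oob <- match.arg(on_oob)
  count <- floor(2 * pi * ring$radius_px / ring$spacing_px)
  if (count < 1) {
    stop(sprintf("ring radius %.3g too small for spacing %.3g: no ROI fits",
                 ring$radius_px, ring$spacing_px))
  }
  theta <- (seq_len(count) - 1) * ring$spacing_px / ring$radius_px
  rows <- round_half_up(ring$center_px[1] + ring$radius_px * sin(theta))
  cols <- round_half_up(ring$center_px[2] + ring$radius_px * cos(theta))
  centers <- cbind(row = as.integer(rows), col = as.integer(cols))
  nr <- ring$roi_size[1]
  nc <- ring$roi_size[2]
  ok <- vapply(seq_len(nrow(centers)), function(k) {
    rr <- patch_range(centers[k, 1], nr)
    cc <- patch_range(centers[k, 2], nc)
    min(rr) >= 1 && max(rr) <= image_shape[1] &&
      min(cc) >= 1 && max(cc) <= image_shape[2]
  }, logical(1))
  if (!all(ok)) {
    if (on_oob == "error") {
      bad <- centers[!ok, , drop = FALSE][1, ]
      stop(sprintf(
        "ROI around center (%d, %d) exceeds the %d x %d image; %s",
        bad[1], bad[2], image_shape[1], image_shape[2],
        "use a smaller radius or enable mask filtering (on_oob = 'drop')"))
    }
    centers <- centers[ok, , drop = FALSE]
    if (nrow(centers) == 0) {
      stop("no ROI on this ring fits inside the image")
    }
  }
  centers
}

#' Filter ROI centers by a pixel mask
#'
#' Keeps only the centers whose full ROI lies entirely in `TRUE` mask
#' pixels, preserving angular order. Used e.g. to restrict an outer ring to
#' the phantom material when the ring extends beyond the phantom boundary.
#'
#' @param centers integer matrix from [ring_roi_centers()].
#' @param mask logical matrix, same shape as the image.
#' @param roi_size ROI side length; scalar or `c(rows, cols)`.
#' @return the filtered center matrix.
#' @export
filter_rois_by_mask <- function(centers, mask, roi_size = 16L) {
  stopifnot(is.matrix(centers), is.matrix(mask))
  roi_size <- as.integer(roi_size)
  if (length(roi_size) == 1) roi_size <- c(roi_size, roi_size)
  keep <- vapply(seq_len(nrow(centers)), function(k) {
    rr <- patch_range(centers[k, 1], roi_size[1])
    cc <- patch_range(centers[k, 2], roi_size[2])
    if (min(rr) < 1 || max(rr) > nrow(mask) ||
        min(cc) < 1 || max(cc) > ncol(mask)) return(FALSE)
    all(mask[rr, cc])
  }, logical(1))
  out <- centers[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("mask filtering removed every ROI; ",
         "use a smaller ring radius or a different mask")
  }
  out
}

#' Extract a square ROI patch
#'
#' Cuts the `roi_size` patch around an integer center. For even sizes the
#' patch covers half-open extents `[center - n/2, center + n/2)` in 0-based
#' coordinates along each axis.
#'
#' @param image numeric matrix.
#' @param center integer `c(row, col)` (1-based).
#' @param roi_size side length; scalar or `c(rows, cols)`.
#' @return an `roi_patch`: list with `origin_px` (1-based top-left corner)
#'   and `values` (the pixel matrix).
#' @export
extract_roi <- function(image, center, roi_size = 16L) {
  stopifnot(is.matrix(image), length(center) == 2)
  roi_size <- as.integer(roi_size)
  if (length(roi_size) == 1) roi_size <- c(roi_size, roi_size)
  center <- as.integer(center)
  rr <- patch_range(center[1], roi_size[1])
  cc <- patch_range(center[2], roi_size[2])
  if (min(rr) < 1 || max(rr) > nrow(image) ||
      min(cc) < 1 || max(cc) > ncol(image)) {
    stop(sprintf("ROI around center (%d, %d) out of bounds for %d x %d image",
                 center[1], center[2], nrow(image), ncol(image)))
  }
  structure(list(origin_px = c(min(rr), min(cc)),
                 values = image[rr, cc, drop = FALSE]),
            class = "roi_patch")
}
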