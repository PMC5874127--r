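#' Image stack of repeated CT scans
#'
#' Container for co-registered axial images of a static phantom: a
#' `rows x cols x n` array of CT numbers (HU) with pixel spacing and an
#' optional slice thickness. The third index is the scan index for repeated
#' acquisitions, or the thin-slice index within one scan when the stack is
#' destined for [reformat_stack()].
#'
#' @param pixels numeric array `rows x cols x n` (a matrix is promoted to a
#'   single-slice stack), values in HU.
#' @param pixel_spacing_mm in-plane pixel spacing in mm; scalar for square
#'   pixels or `c(dx, dy)`.
#' @param slice_thickness_mm slice thickness in mm (`NA` when unknown).
#' @param labels named list of acquisition labels; `condition` (character)
#'   and `dose_mGy` (positive number) are understood by the pipeline.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(pixels, pixel_spacing_mm,
                        slice_thickness_mm = NA_real_, labels = list()) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3) {
    stop("pixels must be a rows x cols x n_scans array")
  }
  if (any(!is.finite(pixels))) stop("pixels must be finite")
  spacing <- as_spacing(pixel_spacing_mm)
  if (!is.na(slice_thickness_mm) && slice_thickness_mm <= 0) {
    stop("slice_thickness_mm must be positive")
  }
  if (!is.null(labels$dose_mGy) && labels$dose_mGy <= 0) {
    stop("dose_mGy label must be positive")
  }
  structure(
    list(pixels = pixels, pixel_spacing_mm = spacing,
         slice_thickness_mm = slice_thickness_mm, labels = labels),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("image_stack: %d scan(s) of %d x %d px, spacing %.6g x %.6g mm",
              d[3], d[1], d[2], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]))
  if (!is.na(x$slice_thickness_mm)) {
    cat(sprintf(", thickness %.4g mm", x$slice_thickness_mm))
  }
  cat("\n")
  if (length(x$labels)) {
    cat("labels:", paste(names(x$labels), unlist(x$labels),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of scans (or slices) in a stack
#' @param stack an `image_stack`.
#' @return integer count along the third dimension.
#' @export
n_scans <- function(stack) dim(stack$pixels)[3]

#' Extract one scan image
#' @param stack an `image_stack`.
#' @param i scan index.
#' @return the i-th image as a matrix.
#' @export
scan_image <- function(stack, i) {
  stopifnot(i >= 1, i <= n_scans(stack))
  stack$pixels[, , i]
}

#' Reformat thin slices to a thicker slice
#'
#' Interprets the stack's third dimension as contiguous thin slices of one
#' scan and averages each run of `group_size` consecutive slices into one
#' output slice (unweighted mean), multiplying the slice thickness
#' accordingly. This reproduces the reformat of 0.625 mm reconstructions
#' into 2.5 mm images (`group_size = 4`) commonly used before NPS analysis;
#' for z-uncorrelated noise it divides the per-pixel noise variance by
#' `group_size`.
#'
#' @param stack an `image_stack` whose slices are thin slices of one scan.
#' @param group_size number of consecutive slices per output slice; must
#'   divide the slice count.
#' @return an `image_stack` with `n/group_size` slices.
#' @export
reformat_stack <- function(stack, group_size) {
  stopifnot(inherits(stack, "image_stack"))
  group_size <- as.integer(group_size)
  if (group_size < 1) stop("group_size must be a positive integer")
  n <- n_scans(stack)
  if (n %% group_size != 0) {
    stop(sprintf(
      "slice count %d is not divisible by group_size %d (remainder %d)",
      n, group_size, n %% group_size))
  }
  if (group_size == 1) return(stack)
  d <- dim(stack$pixels)
  n_out <- n %/% group_size
  out <- array(0, dim = c(d[1], d[2], n_out))
  for (g in seq_len(n_out)) {
    idx <- ((g - 1L) * group_size + 1L):(g * group_size)
    out[, , g] <- apply(stack$pixels[, , idx, drop = FALSE], c(1, 2), mean)
  }
  thick <- if (is.na(stack$slice_thickness_mm)) NA_real_ else
    stack$slice_thickness_mm * group_size
  image_stack(out, stack$pixel_spacing_mm, thick, stack$labels)
}
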