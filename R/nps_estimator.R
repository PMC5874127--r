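#' Noise patch from a pair of consecutive-scan ROIs
#'
#' Isolates stochastic noise from two co-located ROIs of consecutive scans
#' of a static phantom by ratio-detrended subtraction:
#'
#' \deqn{I_{noise} = \left(A - B \, \frac{\bar A}{\bar B}\right) / \sqrt 2}
#'
#' where `A` and `B` are the two patches after adding `mean_offset`, and
#' the bars denote patch means. The ratio removes multiplicative drift
#' (e.g. tube-output fluctuation between scans) together with the
#' deterministic phantom structure; the `1/sqrt(2)` restores the variance
#' of a single image from the difference of two.
#'
#' `mean_offset` shifts the CT-number scale before the ratio is formed. The
#' default +1000 HU maps water-like ROIs (mean near 0 HU) away from zero,
#' where the ratio is numerically unstable, and emulates detrending on the
#' attenuation scale; `mean_offset = 0` reproduces the plain ratio on CT
#' numbers, and the estimator tends to pure subtraction as the offset grows.
#'
#' @param roi_a,roi_b matrices or `roi_patch`es of identical size, from the
#'   same location in two consecutive scans.
#' @param mean_offset HU offset added to both patches before the ratio.
#' @return the noise patch as a matrix (HU).
#' @export
noise_roi_pair <- function(roi_a, roi_b, mean_offset = 1000) {
  a <- patch_values(roi_a)
  b <- patch_values(roi_b)
  if (!all(dim(a) == dim(b))) stop("ROI pair must have identical sizes")
  A <- a + mean_offset
  B <- b + mean_offset
  mB <- mean(B)
  if (abs(mB) <= 1e-6) {
    stop(sprintf(
      "ROI mean %.3g HU is within 1e-6 of -mean_offset (%g); %s",
      mean(b), mean_offset,
      "the ratio detrend is undefined here - adjust mean_offset"))
  }
  (A - B * (mean(A) / mB)) / sqrt(2)
}

#' Build the noise-patch ensemble for one ring
#'
#' For every scan `i = 1..n` and every ROI center on the ring, subtracts
#' the co-located ROI of scan `i + 1` (wrapping `n -> 1`, so each scan
#' contributes once as minuend) via [noise_roi_pair()]. With `n` scans and
#' `m` kept ROIs this yields `n * m` noise patches. Consecutive pairs share
#' scans, so patches are not all independent; this inflates the variance of
#' the ensemble NPS slightly but introduces no bias.
#'
#' @param stack an [image_stack()] with at least 2 scans.
#' @param ring a [ring_spec()].
#' @param mask optional logical matrix; when given, ROIs are dropped unless
#'   fully inside `TRUE` pixels (see [filter_rois_by_mask()]), and
#'   out-of-bounds ring positions are dropped rather than raising.
#' @param mean_offset passed to [noise_roi_pair()].
#' @return a `noise_ensemble`: list with `patches` (list over scans, each a
#'   list of noise matrices), `centers`, `ring`, and `pixel_spacing_mm`.
#' @export
build_noise_ensemble <- function(stack, ring, mask = NULL,
                                 mean_offset = 1000) {
  stopifnot(inherits(stack, "image_stack"), inherits(ring, "ring_spec"))
  n <- n_scans(stack)
  if (n < 2) stop("noise extraction needs at least 2 scans to pair")
  shape <- dim(stack$pixels)[1:2]
  centers <- ring_roi_centers(ring, shape,
                              on_oob = if (is.null(mask)) "error" else "drop")
  if (!is.null(mask)) {
    if (!all(dim(mask) == shape)) stop("mask shape must match the image")
    centers <- filter_rois_by_mask(centers, mask, ring$roi_size)
  }
  patches <- vector("list", n)
  for (i in seq_len(n)) {
    nxt <- if (i == n) 1L else i + 1L
    img_a <- stack$pixels[, , i]
    img_b <- stack$pixels[, , nxt]
    patches[[i]] <- lapply(seq_len(nrow(centers)), function(j) {
      noise_roi_pair(extract_roi(img_a, centers[j, ], ring$roi_size),
                     extract_roi(img_b, centers[j, ], ring$roi_size),
                     mean_offset = mean_offset)
    })
  }
  structure(list(patches = patches, centers = centers, ring = ring,
                 pixel_spacing_mm = stack$pixel_spacing_mm),
            class = "noise_ensemble")
}

#' Flatten a noise ensemble to one list of patches
#' @param ensemble a `noise_ensemble`.
#' @return list of noise-patch matrices across all scans and ROIs.
#' @export
ensemble_patches <- function(ensemble) {
  stopifnot(inherits(ensemble, "noise_ensemble"))
  do.call(c, ensemble$patches)
}

#' 2D NPS from an ensemble of noise patches
#'
#' Averaged 2D periodogram of the patches:
#'
#' \deqn{NPS(f_x, f_y) = \frac{\Delta x \, \Delta y}{N_x N_y}
#'       \; \overline{\left| DFT_{2D}[I_{noise}] \right|^2}}
#'
#' with the unnormalized forward DFT, no window, no zero padding and no
#' mean subtraction beyond the pair detrend. Units are HU^2 mm^2; the bins
#' follow the unshifted DFT layout with frequency axes from [dft_freq()]
#' (bin widths `1/(N dx)` and `1/(N dy)`).
#'
#' @param patches list of equal-size noise matrices (or a
#'   `noise_ensemble`, which is flattened).
#' @param pixel_spacing_mm pixel spacing in mm, scalar or `c(dx, dy)`.
#' @param meta optional list recorded on the result (e.g. ring, scan).
#' @return an `nps2d`: list with `power` (matrix indexed `[fy, fx]`),
#'   `fx`, `fy` (signed 1/mm), `pixel_spacing_mm`, `n_patches`, `meta`.
#' @export
nps2d_from_patches <- function(patches, pixel_spacing_mm, meta = list()) {
  if (inherits(patches, "noise_ensemble")) {
    if (missing(pixel_spacing_mm)) {
      pixel_spacing_mm <- patches$pixel_spacing_mm
    }
    if (is.null(meta$ring)) meta$ring <- patches$ring$radius_px
    patches <- ensemble_patches(patches)
  }
  if (length(patches) == 0) stop("empty patch ensemble")
  spacing <- as_spacing(pixel_spacing_mm)
  d <- dim(patches[[1]])
  acc <- matrix(0, d[1], d[2])
  for (p in patches) {
    if (!all(dim(p) == d)) stop("all patches must share one size")
    acc <- acc + Mod(stats::fft(p))^2
  }
  power <- acc / length(patches) * spacing[1] * spacing[2] / (d[1] * d[2])
  structure(list(power = power,
                 fx = dft_freq(d[2], spacing[1]),
                 fy = dft_freq(d[1], spacing[2]),
                 pixel_spacing_mm = spacing,
                 n_patches = length(patches),
                 meta = meta),
            class = "nps2d")
}

#' @export
print.nps2d <- function(x, ...) {
  cat(sprintf(
    "nps2d: %d x %d bins, df = %.5g x %.5g /mm, %s patch(es), total power %.5g HU^2\n",
    nrow(x$power), ncol(x$power),
    x$fy[2] - x$fy[1], x$fx[2] - x$fx[1],
    ifelse(is.na(x$n_patches), "?", x$n_patches),
    integrated_power(x)))
  invisible(x)
}

#' Average several 2D NPS estimates
#' @param nps_list list of `nps2d` sharing shape and axes.
#' @return the bin-wise mean as an `nps2d`.
#' @export
average_nps2d <- function(nps_list) {
  if (inherits(nps_list, "nps2d")) return(nps_list)
  stopifnot(length(nps_list) >= 1)
  ref <- nps_list[[1]]
  for (x in nps_list) {
    if (!all(dim(x$power) == dim(ref$power)) ||
        max(abs(x$fx - ref$fx)) > 1e-12 || max(abs(x$fy - ref$fy)) > 1e-12) {
      stop("NPS estimates differ in shape or frequency axes")
    }
  }
  power <- Reduce(`+`, lapply(nps_list, `[[`, "power")) / length(nps_list)
  structure(list(power = power, fx = ref$fx, fy = ref$fy,
                 pixel_spacing_mm = ref$pixel_spacing_mm,
                 n_patches = sum(vapply(nps_list, `[[`, numeric(1),
                                        "n_patches")),
                 meta = list(source = "ensemble")),
            class = "nps2d")
}

#' One-sided horizontal and vertical marginal NPS curves
#'
#' Averages the 2D NPS over scans, then over the orthogonal frequency: the
#' vertical curve is the mean over all `fx` bins as a function of `fy`, the
#' horizontal curve the mean over all `fy` bins as a function of `fx`. Both
#' are folded to one-sided axes `0 .. f_Nyquist` using the exact
#' `(fx, fy) -> (-fx, -fy)` symmetry of the real-input periodogram (the bin
#' at `-f` equals the bin at `+f`; no doubling, Nyquist reported once).
#'
#' @param per_scan_nps an `nps2d` or a list of them (e.g. one per scan).
#' @return list with `horizontal` and `vertical`, each an `nps_curve`
#'   (fields `axis`, `frequencies`, `values`).
#' @export
marginal_curves <- function(per_scan_nps) {
  nps <- average_nps2d(per_scan_nps)
  horiz <- colMeans(nps$power)  # mean over fy -> function of fx
  vert <- rowMeans(nps$power)   # mean over fx -> function of fy
  list(
    horizontal = nps_curve("horizontal",
                           one_sided_freq(ncol(nps$power),
                                          nps$pixel_spacing_mm[1]),
                           fold_one_sided(horiz)),
    vertical = nps_curve("vertical",
                         one_sided_freq(nrow(nps$power),
                                        nps$pixel_spacing_mm[2]),
                         fold_one_sided(vert)))
}

#' One-sided marginal NPS curve
#' @param axis `"horizontal"` or `"vertical"`.
#' @param frequencies one-sided frequency axis, 0..Nyquist, 1/mm.
#' @param values NPS values in HU^2 mm^2, same length.
#' @return an `nps_curve`.
#' @export
nps_curve <- function(axis = c("horizontal", "vertical"),
                      frequencies, values) {
  axis <- match.arg(axis)
  if (length(frequencies) != length(values)) {
    stop("frequencies and values must have equal length")
  }
  if (any(values < -1e-12)) stop("NPS curve values must be nonnegative")
  if (is.unsorted(frequencies, strictly = TRUE)) {
    stop("frequencies must be strictly ascending")
  }
  structure(list(axis = axis, frequencies = as.numeric(frequencies),
                 values = pmax(as.numeric(values), 0)),
            class = "nps_curve")
}

#' @export
print.nps_curve <- function(x, ...) {
  cat(sprintf("nps_curve (%s): %d bins, 0..%.4g /mm, peak %.5g HU^2 mm^2\n",
              x$axis, length(x$values), max(x$frequencies), max(x$values)))
  invisible(x)
}
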