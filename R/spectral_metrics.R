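#' Peak frequency of a marginal NPS curve
#'
#' Frequency of the maximum NPS value, excluding the DC bin (the pair
#' detrend leaves a residual DC term that is not noise texture). Ties break
#' toward the lowest frequency. The peak frequency is the standard
#' single-number summary of noise texture: iterative reconstructions shift
#' it toward low frequencies (blotchy texture) relative to FBP.
#'
#' @param curve an `nps_curve`.
#' @return peak frequency in 1/mm.
#' @export
peak_frequency <- function(curve) {
  stopifnot(inherits(curve, "nps_curve"))
  if (length(curve$values) < 2) stop("curve needs at least 2 bins")
  v <- curve$values[-1]
  if (all(v == 0)) stop("all-zero curve has no spectral peak")
  curve$frequencies[-1][which.max(v)]
}

#' Integrated power of a 2D NPS (variance estimate)
#'
#' Sums the NPS over all bins times the bin area `dfx * dfy`. By Parseval's
#' identity this equals the mean squared value of the noise patches, i.e.
#' the pixel noise variance the spectrum decomposes, in HU^2.
#'
#' @param nps an `nps2d`.
#' @return integrated power in HU^2.
#' @export
integrated_power <- function(nps) {
  stopifnot(inherits(nps, "nps2d"))
  dfx <- 1 / (ncol(nps$power) * nps$pixel_spacing_mm[1])
  dfy <- 1 / (nrow(nps$power) * nps$pixel_spacing_mm[2])
  sum(nps$power) * dfx * dfy
}

#' Anisotropy index of a horizontal/vertical curve pair
#'
#' Normalized L1 distance between the two one-sided marginal curves over
#' the non-DC bins:
#'
#' \deqn{AI = \frac{\sum_k |h_k - v_k|}{\sum_k (h_k + v_k)/2}}
#'
#' 0 for identical curves, bounded by 2 (disjoint supports). Scale-free, so
#' conditions of different noise magnitude are comparable. Quantifies how
#' isotropic the noise texture is: the visual "better matched horizontal
#' and vertical curves" becomes a single number.
#'
#' @param h,v `nps_curve`s on the same frequency axis.
#' @return dimensionless index in `[0, 2]`.
#' @export
anisotropy_index <- function(h, v) {
  stopifnot(inherits(h, "nps_curve"), inherits(v, "nps_curve"))
  if (length(h$frequencies) != length(v$frequencies) ||
      max(abs(h$frequencies - v$frequencies)) > 1e-12) {
    stop("curves must share one frequency axis")
  }
  hk <- h$values[-1]
  vk <- v$values[-1]
  denom <- sum((hk + vk) / 2)
  if (denom == 0) stop("both curves are all-zero; anisotropy undefined")
  sum(abs(hk - vk)) / denom
}

#' Per-condition NPS summary
#'
#' Bundles, for one reconstruction/dose condition, the per-ring marginal
#' curves and scalar summaries produced by [run_analysis()].
#'
#' @param condition condition label.
#' @param rings named list (by ring radius) of lists with `horizontal`,
#'   `vertical` (`nps_curve`s) and `nps2d` (ensemble `nps2d`).
#' @param dose_mGy optional dose label.
#' @return a `condition_result` with a `scalars` data.frame of
#'   `ring_radius_px`, `peak_horizontal_per_mm`, `peak_vertical_per_mm`,
#'   `integrated_power_hu2`, `anisotropy_index`.
#' @export
condition_result <- function(condition, rings, dose_mGy = NA_real_) {
  stopifnot(is.character(condition), length(rings) >= 1)
  scalars <- do.call(rbind, lapply(names(rings), function(rn) {
    r <- rings[[rn]]
    data.frame(
      condition = condition,
      ring_radius_px = as.numeric(rn),
      peak_horizontal_per_mm = peak_frequency(r$horizontal),
      peak_vertical_per_mm = peak_frequency(r$vertical),
      integrated_power_hu2 = integrated_power(r$nps2d),
      anisotropy_index = anisotropy_index(r$horizontal, r$vertical))
  }))
  stopifnot(all(is.finite(scalars$integrated_power_hu2)),
            all(scalars$integrated_power_hu2 >= 0),
            all(scalars$anisotropy_index >= 0),
            all(scalars$anisotropy_index <= 2))
  structure(list(condition = condition, dose_mGy = dose_mGy,
                 rings = rings, scalars = scalars),
            class = "condition_result")
}

#' Curve table of a condition result
#' @param result a `condition_result`.
#' @return long data.frame in the [write_curves_csv()] layout.
#' @export
condition_curve_table <- function(result) {
  stopifnot(inherits(result, "condition_result"))
  do.call(rbind, lapply(names(result$rings), function(rn) {
    r <- result$rings[[rn]]
    do.call(rbind, lapply(c("horizontal", "vertical"), function(ax) {
      data.frame(condition = result$condition,
                 ring_radius_px = as.numeric(rn),
                 axis = ax,
                 frequency_per_mm = r[[ax]]$frequencies,
                 nps_hu2mm2 = r[[ax]]$values)
    }))
  }))
}

#' Pairwise comparison of condition results
#'
#' For each requested pair of conditions, tabulates the per-ring, per-axis
#' one-sided curves side by side with the delta against the paired
#' condition, plus a scalar-delta table (peak frequency, integrated power,
#' anisotropy index per ring). Row order is deterministic: pair, condition,
#' ring, axis, frequency.
#'
#' @param results list of `condition_result`s sharing ring set and axes.
#' @param pairs two-column data.frame (`a`, `b`) of condition labels; by
#'   default all unordered pairs of distinct conditions.
#' @return list with data.frames `curves` (columns `pair`, `condition`,
#'   `ring_radius_px`, `axis`, `frequency_per_mm`, `nps_hu2mm2`,
#'   `delta_hu2mm2`) and `scalars`.
#' @export
compare_conditions <- function(results, pairs = NULL) {
  stopifnot(length(results) >= 1)
  names(results) <- vapply(results, `[[`, character(1), "condition")
  if (is.null(pairs)) {
    cn <- names(results)
    if (length(cn) < 2) stop("need at least two conditions or explicit pairs")
    idx <- utils::combn(length(cn), 2)
    pairs <- data.frame(a = cn[idx[1, ]], b = cn[idx[2, ]])
  }
  for (r in results) {
    if (!identical(sort(names(r$rings)), sort(names(results[[1]]$rings)))) {
      stop("conditions have different ring sets")
    }
  }
  curve_rows <- list()
  scalar_rows <- list()
  for (p in seq_len(nrow(pairs))) {
    a <- results[[pairs$a[p]]]
    b <- results[[pairs$b[p]]]
    if (is.null(a) || is.null(b)) stop("pair names a condition not in results")
    pair_id <- paste(a$condition, "vs", b$condition)
    for (rn in sort(as.numeric(names(a$rings)))) {
      rn <- as.character(rn)
      for (ax in c("horizontal", "vertical")) {
        ca <- a$rings[[rn]][[ax]]
        cb <- b$rings[[rn]][[ax]]
        if (length(ca$frequencies) != length(cb$frequencies) ||
            max(abs(ca$frequencies - cb$frequencies)) > 1e-12) {
          stop("conditions have mismatched frequency axes")
        }
        curve_rows[[length(curve_rows) + 1]] <- data.frame(
          pair = pair_id,
          condition = c(rep(a$condition, length(ca$frequencies)),
                        rep(b$condition, length(cb$frequencies))),
          ring_radius_px = as.numeric(rn),
          axis = ax,
          frequency_per_mm = c(ca$frequencies, cb$frequencies),
          nps_hu2mm2 = c(ca$values, cb$values),
          delta_hu2mm2 = c(ca$values - cb$values, cb$values - ca$values))
      }
      sa <- a$scalars[a$scalars$ring_radius_px == as.numeric(rn), ]
      sb <- b$scalars[b$scalars$ring_radius_px == as.numeric(rn), ]
      scalar_rows[[length(scalar_rows) + 1]] <- data.frame(
        pair = pair_id, ring_radius_px = as.numeric(rn),
        delta_peak_horizontal_per_mm =
          sa$peak_horizontal_per_mm - sb$peak_horizontal_per_mm,
        delta_peak_vertical_per_mm =
          sa$peak_vertical_per_mm - sb$peak_vertical_per_mm,
        delta_integrated_power_hu2 =
          sa$integrated_power_hu2 - sb$integrated_power_hu2,
        delta_anisotropy_index = sa$anisotropy_index - sb$anisotropy_index)
    }
  }
  curves <- do.call(rbind, curve_rows)
  ord <- order(curves$pair, curves$condition, curves$ring_radius_px,
               curves$axis, curves$frequency_per_mm)
  list(curves = curves[ord, ], scalars = do.call(rbind, scalar_rows))
}
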