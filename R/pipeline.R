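#' Analysis configuration
#'
#' Validated bundle of everything one NPS run needs: the input stacks with
#' their condition labels, the ring geometry, the detrend offset and the
#' output location. Defaults follow the standard patient-sized-phantom
#' protocol: rings of radius 50, 90, 120 and 180 pixels, 16 x 16 px ROIs
#' spaced 8 px along the circumference.
#'
#' @param stacks named list of [image_stack()]s (names become condition
#'   labels), or a list of lists `list(stack =, condition =, dose_mGy =)`.
#' @param center_px ring center `c(row, col)`; image center by default.
#' @param radii ring radii in pixels; positive and distinct.
#' @param roi_size ROI side length in pixels.
#' @param spacing_px ROI center-to-center arc spacing in pixels.
#' @param mean_offset HU offset for the ratio detrend, see
#'   [noise_roi_pair()].
#' @param mask optional logical matrix restricting ROI placement.
#' @param out_dir optional output directory for CSVs and the run log.
#' @return an `analysis_config`.
#' @export
analysis_config <- function(stacks, center_px = NULL,
                            radii = c(50, 90, 120, 180), roi_size = 16L,
                            spacing_px = 8, mean_offset = 1000,
                            mask = NULL, out_dir = NULL) {
  if (length(stacks) < 1) stop("need at least one input stack")
  if (any(radii <= 0)) stop("ring radii must be positive")
  if (anyDuplicated(radii)) stop("ring radii must be distinct")
  entries <- lapply(seq_along(stacks), function(k) {
    s <- stacks[[k]]
    if (inherits(s, "image_stack")) {
      cond <- if (!is.null(names(stacks)) && nzchar(names(stacks)[k])) {
        names(stacks)[k]
      } else if (!is.null(s$labels$condition)) {
        s$labels$condition
      } else {
        paste0("condition_", k)
      }
      list(stack = s, condition = cond,
           dose_mGy = if (is.null(s$labels$dose_mGy)) NA_real_
                      else s$labels$dose_mGy)
    } else {
      stopifnot(inherits(s$stack, "image_stack"), is.character(s$condition))
      list(stack = s$stack, condition = s$condition,
           dose_mGy = if (is.null(s$dose_mGy)) NA_real_ else s$dose_mGy)
    }
  })
  conds <- vapply(entries, `[[`, character(1), "condition")
  if (anyDuplicated(conds)) stop("condition labels must be unique")
  structure(list(stacks = entries, center_px = center_px,
                 radii = as.numeric(radii), roi_size = as.integer(roi_size),
                 spacing_px = spacing_px, mean_offset = mean_offset,
                 mask = mask, out_dir = out_dir),
            class = "analysis_config")
}

# Effective parameters (defaults included) for the run log.
config_log <- function(config) {
  list(radii_px = config$radii,
       roi_size_px = config$roi_size,
       spacing_px = config$spacing_px,
       mean_offset_hu = config$mean_offset,
       center_px = if (is.null(config$center_px)) "image center"
                   else config$center_px,
       mask = !is.null(config$mask),
       conditions = lapply(config$stacks, function(e) {
         list(condition = e$condition, dose_mGy = e$dose_mGy,
              n_scans = n_scans(e$stack),
              image_px = dim(e$stack$pixels)[1:2],
              pixel_spacing_mm = e$stack$pixel_spacing_mm)
       }))
}

#' Run the ring-sampled NPS analysis
#'
#' End-to-end estimation for every condition in the config: per ring,
#' build the consecutive-pair noise ensemble, form the per-scan 2D NPS
#' estimates, average them into the ensemble NPS, fold the one-sided
#' horizontal/vertical marginal curves, and summarise peak frequency,
#' integrated power and anisotropy index. A failing condition is recorded
#' (with its error) without stopping the others. When `out_dir` is set,
#' writes per-condition curve CSVs, a scalar summary CSV and a YAML run
#' log of every effective parameter.
#'
#' @param config an [analysis_config()].
#' @return named list of `condition_result`s (failed conditions carry a
#'   `condition_error`).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  results <- list()
  errors <- list()
  for (entry in config$stacks) {
    res <- tryCatch(
      analyze_condition(entry, config),
      error = function(e) {
        structure(list(condition = entry$condition,
                       message = conditionMessage(e)),
                  class = "condition_error")
      })
    results[[entry$condition]] <- res
    if (inherits(res, "condition_error")) {
      errors[[entry$condition]] <- res$message
    }
  }
  if (!is.null(config$out_dir)) {
    write_analysis_outputs(results, config, errors)
  }
  results
}

analyze_condition <- function(entry, config) {
  stack <- entry$stack
  shape <- dim(stack$pixels)[1:2]
  center <- if (is.null(config$center_px)) (shape + 1) / 2 else config$center_px
  rings <- list()
  for (radius in config$radii) {
    ring <- ring_spec(center, radius, config$roi_size, config$spacing_px)
    ensemble <- build_noise_ensemble(stack, ring, mask = config$mask,
                                     mean_offset = config$mean_offset)
    per_scan <- lapply(ensemble$patches, function(scan_patches) {
      nps2d_from_patches(scan_patches, stack$pixel_spacing_mm,
                         meta = list(ring = radius))
    })
    ens_nps <- average_nps2d(per_scan)
    curves <- marginal_curves(per_scan)
    rings[[as.character(radius)]] <- list(horizontal = curves$horizontal,
                                          vertical = curves$vertical,
                                          nps2d = ens_nps)
  }
  condition_result(entry$condition, rings, dose_mGy = entry$dose_mGy)
}

write_analysis_outputs <- function(results, config, errors) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- Filter(function(r) inherits(r, "condition_result"), results)
  for (res in ok) {
    write_curves_csv(condition_curve_table(res),
                     file.path(config$out_dir,
                               paste0("curves_", res$condition, ".csv")))
  }
  if (length(ok)) {
    scalars <- do.call(rbind, lapply(ok, `[[`, "scalars"))
    utils::write.csv(scalars,
                     file.path(config$out_dir, "scalar_summary.csv"),
                     row.names = FALSE)
  }
  log <- config_log(config)
  log$errors <- if (length(errors)) errors else "none"
  yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))
  invisible(NULL)
}

#' Compare analysed conditions and write comparison tables
#'
#' Thin orchestration over [compare_conditions()]: drops failed
#' conditions, builds the comparison tables and, when `out_dir` is given,
#' writes one curve-comparison CSV per pair plus a scalar-delta CSV.
#'
#' @param results output of [run_analysis()] (or a list of
#'   `condition_result`s).
#' @param pairs optional two-column data.frame (`a`, `b`) of condition
#'   labels; all unordered pairs by default.
#' @param out_dir optional output directory.
#' @return the [compare_conditions()] list (`curves`, `scalars`).
#' @export
run_compare <- function(results, pairs = NULL, out_dir = NULL) {
  ok <- Filter(function(r) inherits(r, "condition_result"), results)
  cmp <- compare_conditions(ok, pairs = pairs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (pair_id in unique(cmp$curves$pair)) {
      fname <- paste0("compare_", gsub("[^A-Za-z0-9._-]+", "_", pair_id),
                      ".csv")
      utils::write.csv(cmp$curves[cmp$curves$pair == pair_id, ],
                       file.path(out_dir, fname), row.names = FALSE)
    }
    utils::write.csv(cmp$scalars, file.path(out_dir, "scalar_deltas.csv"),
                     row.names = FALSE)
  }
  cmp
}
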