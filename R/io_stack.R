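#' Read an image stack from disk
#'
#' Assembles an [image_stack()] from one of three on-disk layouts:
#'
#' * `dicom_series` — a directory of uncompressed little-endian DICOM
#'   slices, one per scan, stacked in file-name order; pixel spacing and
#'   slice thickness are taken from the metadata when present.
#' * `tiff_stack` — a multi-page TIFF, one page per scan (no spacing
#'   metadata; `pixel_spacing_mm` must be supplied).
#' * `array_stack` — the plain-text stack format written by
#'   [write_array_stack()] (header with dimensions, spacing and thickness,
#'   then whitespace-separated values).
#'
#' @param path file (tiff/array stack) or directory (DICOM series).
#' @param format one of `"dicom_series"`, `"array_stack"`, `"tiff_stack"`.
#' @param pixel_spacing_mm fallback spacing in mm when the format carries
#'   none; for DICOM it overrides only files lacking PixelSpacing.
#' @param labels named list of condition labels attached to the stack.
#' @return an [image_stack()], scans ordered by file/page order.
#' @export
read_image_stack <- function(path,
                             format = c("array_stack", "tiff_stack",
                                        "dicom_series"),
                             pixel_spacing_mm = NULL, labels = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  switch(format,
    dicom_series = read_dicom_series(path, pixel_spacing_mm, labels),
    tiff_stack = read_tiff_stack(path, pixel_spacing_mm, labels),
    array_stack = read_array_stack(path, labels))
}

read_dicom_series <- function(dir, pixel_spacing_mm = NULL, labels = list()) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM series directory: ", dir)
  slices <- lapply(files, read_dicom_slice)
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("mixed matrix sizes across DICOM series: ", dir)
  }
  spacings <- vapply(slices, function(s) s$pixel_spacing_mm, numeric(2))
  spacing <- spacings[, 1]
  if (any(is.na(spacing))) {
    if (is.null(pixel_spacing_mm)) {
      stop("DICOM series lacks PixelSpacing and no pixel_spacing_mm ",
           "fallback was configured: ", dir)
    }
    spacing <- as_spacing(pixel_spacing_mm)
  } else if (any(abs(spacings - spacing) > 1e-9)) {
    stop("inconsistent pixel spacing across DICOM series: ", dir)
  }
  thick <- slices[[1]]$slice_thickness_mm
  pixels <- array(unlist(lapply(slices, `[[`, "pixels")),
                  dim = c(dim(slices[[1]]$pixels), length(slices)))
  image_stack(pixels, spacing, thick, labels)
}

read_tiff_stack <- function(path, pixel_spacing_mm, labels = list()) {
  if (is.null(pixel_spacing_mm)) {
    stop("tiff_stack carries no spacing metadata; supply pixel_spacing_mm")
  }
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # 32 bits/sample is float (read natively); 8/16-bit integer pages are
  # re-read as stored integers rather than the default [0,1] scaling
  bps <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bps) || bps != 32L) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims != dims[, 1])) stop("mixed page sizes in TIFF stack: ", path)
  pixels <- array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
  image_stack(pixels, pixel_spacing_mm, labels = labels)
}

#' Write / read the plain-text array-stack format
#'
#' A self-describing text format for small stacks: four header lines
#' (`ringnps array_stack 1`, `dims: rows cols n`, `pixel_spacing_mm: dx dy`,
#' `slice_thickness_mm: t`) followed by the pixel values of each scan in
#' row-major order, whitespace-separated, full double precision.
#'
#' @param stack an [image_stack()].
#' @param path output (input) file path.
#' @return `write_array_stack` returns `path` invisibly; `read_array_stack`
#'   returns an [image_stack()].
#' @export
write_array_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ringnps array_stack 1",
               paste("dims:", d[1], d[2], d[3]),
               paste("pixel_spacing_mm:",
                     sprintf("%.17g", stack$pixel_spacing_mm[1]),
                     sprintf("%.17g", stack$pixel_spacing_mm[2])),
               paste("slice_thickness_mm:",
                     sprintf("%.17g", stack$slice_thickness_mm))), con)
  for (i in seq_len(d[3])) {
    # row-major per scan: write the transpose so rows are contiguous
    writeLines(paste(sprintf("%.17g", t(stack$pixels[, , i])),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_array_stack
#' @param labels named list of condition labels attached to the stack.
#' @export
read_array_stack <- function(path, labels = list()) {
  lines <- readLines(path, n = 4)
  if (length(lines) < 4 || !startsWith(lines[1], "ringnps array_stack")) {
    stop("not a ringnps array_stack file: ", path)
  }
  d <- as.integer(strsplit(lines[2], "\\s+")[[1]][-1])
  spacing <- as.numeric(strsplit(lines[3], "\\s+")[[1]][-1])
  thick_str <- strsplit(lines[4], "\\s+")[[1]][-1]
  thick <- if (identical(thick_str, "NA")) NA_real_ else as.numeric(thick_str)
  vals <- scan(path, skip = 4, quiet = TRUE)
  if (length(vals) != prod(d)) {
    stop(sprintf("array_stack %s: expected %d values, found %d",
                 path, prod(d), length(vals)))
  }
  pixels <- array(0, dim = d)
  per <- d[1] * d[2]
  for (i in seq_len(d[3])) {
    pixels[, , i] <- matrix(vals[((i - 1) * per + 1):(i * per)],
                            nrow = d[1], byrow = TRUE)
  }
  image_stack(pixels, spacing, thick, labels)
}

#' Write / read NPS curve tables as CSV
#'
#' Long-format serialization of one-sided marginal NPS curves: columns
#' `condition`, `ring_radius_px`, `axis` (`horizontal`/`vertical`),
#' `frequency_per_mm`, `nps_hu2mm2`. Values are written with 17 significant
#' digits so a read-back reproduces them exactly.
#'
#' @param table data.frame with the five columns above.
#' @param path CSV path.
#' @return `write_curves_csv` returns `path` invisibly; `read_curves_csv`
#'   returns the table with numeric columns restored.
#' @export
write_curves_csv <- function(table, path) {
  required <- c("condition", "ring_radius_px", "axis",
                "frequency_per_mm", "nps_hu2mm2")
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("curve table must be a nonempty data.frame")
  }
  if (!all(required %in% names(table))) {
    stop("curve table must have columns: ", paste(required, collapse = ", "))
  }
  if (any(table$nps_hu2mm2 < 0)) stop("nps values must be nonnegative")
  out <- table[, required]
  out$frequency_per_mm <- sprintf("%.17g", out$frequency_per_mm)
  out$nps_hu2mm2 <- sprintf("%.17g", out$nps_hu2mm2)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$ring_radius_px <- as.numeric(tab$ring_radius_px)
  tab$frequency_per_mm <- as.numeric(tab$frequency_per_mm)
  tab$nps_hu2mm2 <- as.numeric(tab$nps_hu2mm2)
  tab
}

#' Export a 2D NPS as a float TIFF with a text sidecar
#'
#' Writes `power / scale` as a 32-bit float TIFF (TIFF float storage only
#' round-trips values in `[0, 1]`) with `scale = max(power)` and the
#' frequency axes recorded in `<path>.axes.txt`. [read_nps2d_tiff()]
#' reverses the export.
#'
#' @param nps an `nps2d` object from [nps2d_from_patches()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_nps2d_tiff <- function(nps, path) {
  stopifnot(inherits(nps, "nps2d"))
  scale <- max(nps$power)
  img <- if (scale > 0) nps$power / scale else nps$power
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  sidecar <- paste0(path, ".axes.txt")
  writeLines(c("ringnps nps2d sidecar 1",
               "units: HU^2 mm^2",
               paste("scale_hu2mm2:", sprintf("%.17g", scale)),
               paste("pixel_spacing_mm:",
                     sprintf("%.17g", nps$pixel_spacing_mm[1]),
                     sprintf("%.17g", nps$pixel_spacing_mm[2])),
               paste("fx_per_mm:", paste(sprintf("%.17g", nps$fx),
                                         collapse = " ")),
               paste("fy_per_mm:", paste(sprintf("%.17g", nps$fy),
                                         collapse = " "))),
             sidecar)
  invisible(path)
}

#' @rdname write_nps2d_tiff
#' @export
read_nps2d_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  lines <- readLines(paste0(path, ".axes.txt"))
  get_nums <- function(prefix) {
    as.numeric(strsplit(sub(prefix, "", lines[startsWith(lines, prefix)]),
                        "\\s+")[[1]][-1])
  }
  scale <- as.numeric(sub("scale_hu2mm2: ", "",
                          lines[startsWith(lines, "scale_hu2mm2:")]))
  spacing <- get_nums("pixel_spacing_mm:")
  structure(list(power = img * scale,
                 fx = get_nums("fx_per_mm:"),
                 fy = get_nums("fy_per_mm:"),
                 pixel_spacing_mm = c(spacing[1], spacing[2]),
                 n_patches = NA_integer_, meta = list(source = path)),
            class = "nps2d")
}
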