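# Minimal DICOM reader for uncompressed single-frame CT slices.
#
# Supports the two uncompressed little-endian transfer syntaxes (explicit
# VR 1.2.840.10008.1.2.1 and implicit VR 1.2.840.10008.1.2). Compressed
# pixel data, big-endian files and undefined-length sequences are rejected.
# Only the handful of attributes the NPS pipeline needs are interpreted;
# everything else is skipped by length.

dcm_uint16 <- function(r, i) {
  as.integer(r[i]) + 256L * as.integer(r[i + 1L])
}

dcm_uint32 <- function(r, i) {
  as.numeric(r[i]) + 256 * as.numeric(r[i + 1L]) +
    65536 * as.numeric(r[i + 2L]) + 16777216 * as.numeric(r[i + 3L])
}

dcm_string <- function(r, i, len) {
  if (len == 0) return("")
  v <- r[i:(i + len - 1L)]
  v <- v[v != as.raw(0)]  # UI values are NUL-padded to even length
  trimws(rawToChar(v))
}

# VRs that use the 4-byte length form in explicit encoding.
.dcm_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

#' Read one uncompressed DICOM slice
#'
#' Parses a single-frame little-endian DICOM file and returns the rescaled
#' pixel matrix in HU together with the geometry attributes used by the NPS
#' pipeline.
#'
#' @param path path to a DICOM file.
#' @return list with `pixels` (matrix, HU, rows x cols),
#'   `pixel_spacing_mm` as `c(dx, dy)`, `slice_thickness_mm` (or `NA`),
#'   and `instance_number` (or `NA`).
#' @export
read_dicom_slice <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 140) stop("not a DICOM file (too short): ", path)
  if (rawToChar(r[129:132]) != "DICM") {
    stop("missing DICM marker (raw datasets without preamble unsupported): ",
         path)
  }

  attrs <- list(rows = NA, cols = NA, spacing = c(NA, NA),
                thickness = NA_real_, bits = 16L, signed = FALSE,
                slope = 1, intercept = 0, instance = NA_real_,
                transfer_syntax = "1.2.840.10008.1.2.1")
  pixel_off <- NA
  pixel_len <- NA

  pos <- 133L           # first byte after the DICM marker
  explicit <- TRUE      # file meta group (0002) is always explicit VR
  n <- length(r)
  while (pos + 7L <= n) {
    group <- dcm_uint16(r, pos)
    elem <- dcm_uint16(r, pos + 2L)
    if (group != 2L && attrs$transfer_syntax == "1.2.840.10008.1.2") {
      explicit <- FALSE
    }
    if (explicit) {
      vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
      if (vr %in% .dcm_long_vrs) {
        len <- dcm_uint32(r, pos + 8L)
        val <- pos + 12L
      } else {
        len <- dcm_uint16(r, pos + 6L)
        val <- pos + 8L
      }
    } else {
      len <- dcm_uint32(r, pos + 4L)
      val <- pos + 8L
    }
    if (len == 4294967295) {
      stop("undefined-length element (",
           sprintf("%04X,%04X", group, elem),
           ") unsupported: ", path)
    }

    if (group == 2L && elem == 16L) {          # (0002,0010) TransferSyntaxUID
      ts <- dcm_string(r, val, len)
      if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")) {
        stop("unsupported transfer syntax ", ts,
             " (only uncompressed little endian): ", path)
      }
      attrs$transfer_syntax <- ts
    } else if (group == 40L) {                 # group 0028
      if (elem == 16L) attrs$rows <- dcm_uint16(r, val)
      if (elem == 17L) attrs$cols <- dcm_uint16(r, val)
      if (elem == 48L) {                       # PixelSpacing: row\col spacing
        sp <- as.numeric(strsplit(dcm_string(r, val, len), "\\\\")[[1]])
        attrs$spacing <- c(sp[2], sp[1])       # store as (dx, dy)
      }
      if (elem == 256L) attrs$bits <- dcm_uint16(r, val)
      if (elem == 259L) attrs$signed <- dcm_uint16(r, val) == 1L
      if (elem == 4178L) attrs$intercept <- as.numeric(dcm_string(r, val, len))
      if (elem == 4179L) attrs$slope <- as.numeric(dcm_string(r, val, len))
    } else if (group == 24L && elem == 80L) {  # (0018,0050) SliceThickness
      attrs$thickness <- as.numeric(dcm_string(r, val, len))
    } else if (group == 32L && elem == 19L) {  # (0020,0013) InstanceNumber
      attrs$instance <- as.numeric(dcm_string(r, val, len))
    } else if (group == 32736L && elem == 16L) {  # (7FE0,0010) PixelData
      pixel_off <- val
      pixel_len <- len
      break
    }
    pos <- val + len
  }

  if (is.na(pixel_off)) stop("no PixelData element found: ", path)
  if (is.na(attrs$rows) || is.na(attrs$cols)) {
    stop("missing Rows/Columns attributes: ", path)
  }
  if (attrs$bits != 16L) {
    stop("only 16-bit pixel data supported, got ", attrs$bits, ": ", path)
  }
  npix <- attrs$rows * attrs$cols
  if (pixel_len < 2 * npix) stop("truncated PixelData: ", path)
  con <- rawConnection(r[pixel_off:(pixel_off + 2 * npix - 1L)])
  on.exit(close(con))
  stored <- readBin(con, "integer", n = npix, size = 2L,
                    signed = attrs$signed, endian = "little")
  hu <- stored * attrs$slope + attrs$intercept
  # DICOM pixel order is row-major (first row left to right)
  pixels <- matrix(hu, nrow = attrs$rows, ncol = attrs$cols, byrow = TRUE)
  list(pixels = pixels,
       pixel_spacing_mm = attrs$spacing,
       slice_thickness_mm = attrs$thickness,
       instance_number = attrs$instance)
}
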