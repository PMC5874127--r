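# Byte-level construction of minimal DICOM files for reader tests.
# The package deliberately does not write DICOM (out of scope), so the
# fixture writer lives here.

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32le <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256,
           (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

dcm_pad <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
  r
}

# Explicit-VR short-form element (DS, IS, US, UI, CS ...)
dcm_elem <- function(group, elem, vr, value_raw) {
  c(u16le(group), u16le(elem), charToRaw(vr),
    u16le(length(value_raw)), value_raw)
}

# Implicit-VR element
dcm_elem_implicit <- function(group, elem, value_raw) {
  c(u16le(group), u16le(elem), u32le(length(value_raw)), value_raw)
}

# Build a single-frame 16-bit CT DICOM file. `pixels` is an HU matrix;
# stored values are pixels - intercept (slope 1), written signed LE.
write_test_dicom <- function(path, pixels, spacing_mm = c(0.703125, 0.703125),
                             thickness_mm = 0.625, instance = 1,
                             intercept = -1024, implicit = FALSE,
                             omit_spacing = FALSE) {
  ts <- if (implicit) "1.2.840.10008.1.2" else "1.2.840.10008.1.2.1"
  meta <- dcm_elem(0x0002, 0x0010, "UI", dcm_pad(ts))
  el <- if (implicit) {
    function(g, e, vr, v) dcm_elem_implicit(g, e, v)
  } else {
    dcm_elem
  }
  # spacing is stored row\col (dy\dx)
  body <- c(
    el(0x0018, 0x0050, "DS", dcm_pad(format(thickness_mm))),
    el(0x0020, 0x0013, "IS", dcm_pad(format(instance))),
    el(0x0028, 0x0010, "US", u16le(nrow(pixels))),
    el(0x0028, 0x0011, "US", u16le(ncol(pixels))))
  if (!omit_spacing) {
    body <- c(body, el(0x0028, 0x0030, "DS",
                       dcm_pad(paste0(format(spacing_mm[2]), "\\",
                                      format(spacing_mm[1])))))
  }
  body <- c(body,
    el(0x0028, 0x0100, "US", u16le(16)),
    el(0x0028, 0x0103, "US", u16le(1)),
    el(0x0028, 0x1052, "DS", dcm_pad(format(intercept))),
    el(0x0028, 0x1053, "DS", dcm_pad("1")))
  stored <- as.integer(round(t(pixels) - intercept))  # row-major order
  stopifnot(all(stored >= -32768), all(stored <= 32767))
  con <- rawConnection(raw(0), "w")
  writeBin(stored, con, size = 2L, endian = "little")
  pix_raw <- rawConnectionValue(con)
  close(con)
  pix_elem <- if (implicit) {
    c(u16le(0x7FE0), u16le(0x0010), u32le(length(pix_raw)), pix_raw)
  } else {
    c(u16le(0x7FE0), u16le(0x0010), charToRaw("OW"), as.raw(c(0, 0)),
      u32le(length(pix_raw)), pix_raw)
  }
  bytes <- c(raw(128), charToRaw("DICM"), meta, body, pix_elem)
  writeBin(bytes, path)
  invisible(path)
}

# Write a whole series directory of HU matrices.
write_test_dicom_series <- function(dir, slices, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(slices)) {
    write_test_dicom(file.path(dir, sprintf("slice_%03d.dcm", i)),
                     slices[[i]], instance = i, ...)
  }
  invisible(dir)
}
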