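# Minimal DICOM writer for test fixtures: Part 10, explicit VR little
# endian, one 16-bit single-frame slice per file. Only used to build inputs
# for the series reader.

dcm_write_slice <- function(path, pixels, series_uid = "1.2.3.4",
                            slice_z = 0, instance = 1L,
                            pixel_spacing = c(0.7, 0.7),
                            slice_thickness = 1.25,
                            slope = 1, intercept = -1024,
                            signed = FALSE) {
  pad_even <- function(s) if (nchar(s) %% 2 == 1) paste0(s, " ") else s
  el_short <- function(group, elem, vr, value_raw) {
    c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
      charToRaw(vr),
      writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
  el_long <- function(group, elem, vr, value_raw) {
    c(writeBin(c(group, elem), raw(), size = 2, endian = "little"),
      charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  }
  txt <- function(s) charToRaw(pad_even(s))
  us <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")

  meta <- c(
    el_short(0x0002L, 0x0010L, "UI", txt("1.2.840.10008.1.2.1"))
  )
  rows <- nrow(pixels); cols <- ncol(pixels)
  stored <- as.integer(round(t(pixels)))  # row-major on disk
  body <- c(
    el_short(0x0018L, 0x0050L, "DS", txt(format(slice_thickness))),
    el_short(0x0020L, 0x000DL, "UI", txt("9.8.7")),
    el_short(0x0020L, 0x000EL, "UI", txt(series_uid)),
    el_short(0x0020L, 0x0013L, "IS", txt(format(instance))),
    el_short(0x0020L, 0x0032L, "DS",
             txt(sprintf("0\\0\\%s", format(slice_z)))),
    el_short(0x0028L, 0x0010L, "US", us(rows)),
    el_short(0x0028L, 0x0011L, "US", us(cols)),
    el_short(0x0028L, 0x0030L, "DS",
             txt(sprintf("%s\\%s", format(pixel_spacing[1]),
                         format(pixel_spacing[2])))),
    el_short(0x0028L, 0x0100L, "US", us(16L)),
    el_short(0x0028L, 0x0103L, "US", us(if (signed) 1L else 0L)),
    el_short(0x0028L, 0x1052L, "DS", txt(format(intercept))),
    el_short(0x0028L, 0x1053L, "DS", txt(format(slope))),
    el_long(0x7FE0L, 0x0010L, "OW",
            writeBin(stored, raw(), size = 2, endian = "little"))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# Write a small coherent series of constant-plus-ramp slices; returns the
# directory and the HU array ((slice, row, col)) the reader should produce.
dcm_write_series <- function(dir, n_slices = 3, rows = 8, cols = 10,
                             series_uid = "1.2.3.4", dz = 1.25,
                             intercept = -1024) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hu <- array(NA_real_, c(n_slices, rows, cols))
  for (s in seq_len(n_slices)) {
    stored <- outer(seq_len(rows), seq_len(cols), function(r, c) {
      200 + 10 * s + r + c
    })
    dcm_write_slice(file.path(dir, sprintf("slice%02d.dcm", s)), stored,
                    series_uid = series_uid, slice_z = (s - 1) * dz,
                    instance = s, intercept = intercept)
    hu[s, , ] <- stored + intercept
  }
  list(dir = dir, hu = hu)
}
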