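# shared fixtures: small phantoms, hand-built masks, a minimal DICOM writer

toy_phantom_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(shape = c(32L, 48L, 48L), aorta_radius = 8, lm_radius = 2,
         rca_radius = 1.6, noise_sd = 35, seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

# empty label mask of the given shape
blank_mask <- function(shape = c(16L, 16L, 16L),
                       spacing = c(1, 1, 1)) {
  label_mask(array(0L, dim = shape), spacing)
}

# write one minimal explicit-VR little-endian DICOM file (CT slice)
write_test_dicom <- function(path, pixels, rows, cols,
                             pixel_spacing = c(0.66, 0.66),
                             position = c(0, 0, 0),
                             orientation = c(1, 0, 0, 0, 1, 0),
                             slope = 1, intercept = -1024,
                             thickness = 0.9,
                             drop_pixel_spacing = FALSE) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  elem <- function(group, el, vr, payload) {
    w16(group); w16(el)
    writeChar(vr, con, nchars = 2, eos = NULL)
    if (vr %in% c("OB", "OW")) {
      w16(0L)
      writeBin(as.integer(length(payload)), con, size = 4,
               endian = "little")
    } else {
      w16(length(payload))
    }
    writeBin(payload, con)
  }
  str_payload <- function(s) {
    b <- charToRaw(s)
    if (length(b) %% 2 == 1) b <- c(b, charToRaw(" "))
    b
  }
  u16_payload <- function(x) writeBin(as.integer(x), raw(),
                                      size = 2, endian = "little")
  writeBin(raw(128), con)
  writeChar("DICM", con, nchars = 4, eos = NULL)
  elem(0x0002, 0x0010, "UI", str_payload("1.2.840.10008.1.2.1"))
  elem(0x0018, 0x0050, "DS", str_payload(format(thickness)))
  elem(0x0020, 0x0032, "DS",
       str_payload(paste(position, collapse = "\\")))
  elem(0x0020, 0x0037, "DS",
       str_payload(paste(orientation, collapse = "\\")))
  elem(0x0028, 0x0010, "US", u16_payload(rows))
  elem(0x0028, 0x0011, "US", u16_payload(cols))
  if (!drop_pixel_spacing)
    elem(0x0028, 0x0030, "DS",
         str_payload(paste(pixel_spacing, collapse = "\\")))
  elem(0x0028, 0x0100, "US", u16_payload(16L))
  elem(0x0028, 0x0103, "US", u16_payload(0L))
  elem(0x0028, 0x1052, "DS", str_payload(format(intercept)))
  elem(0x0028, 0x1053, "DS", str_payload(format(slope)))
  # pixels arrive as a (y, x) matrix; DICOM stores row-major
  stopifnot(length(pixels) == rows * cols)
  px <- as.integer(t(matrix(pixels, nrow = rows)))
  elem(0x7FE0, 0x0010, "OW",
       writeBin(px, raw(), size = 2, endian = "little"))
  invisible(path)
}

# write a small DICOM series of constant-HU axial slices
write_test_dicom_series <- function(dir, hu_values, rows = 8L, cols = 8L,
                                    dz = 0.9, intercept = -1024, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(hu_values)) {
    stored <- matrix(hu_values[i] - intercept, rows, cols)
    write_test_dicom(file.path(dir, sprintf("slice%02d.dcm", i)),
                     stored, rows, cols,
                     position = c(0, 0, (i - 1) * dz),
                     intercept = intercept, ...)
  }
  invisible(dir)
}
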