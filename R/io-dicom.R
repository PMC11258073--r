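#' Read a DICOM series directory as a CT volume
#'
#' A deliberately small reader for uncompressed explicit-VR little-endian
#' CT series (transfer syntax 1.2.840.10008.1.2.1), sufficient for
#' axis-aligned axial acquisitions: slices are sorted by Image Position
#' (Patient) along the slice normal, Rescale Slope/Intercept are applied to
#' yield HU, and in-plane spacing is taken from Pixel Spacing with the
#' through-plane spacing from consecutive slice positions. Compressed or
#' implicit-VR files, missing spacing, mixed matrix sizes and non-uniform
#' slice gaps are all reported as errors naming the offending instances.
#'
#' @param dir Directory containing one series (all regular files are read).
#' @return A `ct_volume` in HU with (z, y, x) axis order.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, parse_dicom_file)

  rows <- vapply(slices, `[[`, 0, "rows")
  cols <- vapply(slices, `[[`, 0, "cols")
  if (length(unique(rows)) > 1L || length(unique(cols)) > 1L)
    stop("inconsistent DICOM series: matrix size differs in ",
         paste(basename(files[rows != rows[1] | cols != cols[1]]),
               collapse = ", "))
  ps <- slices[[1]]$pixel_spacing
  for (s in slices)
    if (max(abs(s$pixel_spacing - ps)) > 1e-6)
      stop("inconsistent DICOM series: PixelSpacing differs across instances")

  # axial, axis-aligned orientation required: row dir (1,0,0), col dir (0,1,0)
  for (i in seq_along(slices)) {
    iop <- slices[[i]]$orientation
    if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-3)
      stop("DICOM instance ", basename(files[i]),
           " is not axis-aligned axial; reorient before reading")
  }
  zpos <- vapply(slices, function(s) s$position[3], 0)
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]; files <- files[ord]
  if (length(slices) > 1L) {
    dz <- diff(zpos)
    if (any(dz <= 0))
      stop("inconsistent DICOM series: duplicate slice positions in ",
           paste(basename(files[c(FALSE, dz <= 0)]), collapse = ", "))
    if (max(dz) - min(dz) > 1e-3)
      stop("inconsistent DICOM series: non-uniform slice spacing (",
           paste(format(range(dz), digits = 6), collapse = " vs "), " mm)")
    slice_mm <- mean(dz)
  } else {
    slice_mm <- slices[[1]]$slice_thickness
    if (!is.finite(slice_mm) || slice_mm <= 0)
      stop("single-slice series without a positive SliceThickness")
  }

  nz <- length(slices); ny <- rows[1]; nx <- cols[1]
  vol <- array(0, dim = c(nz, ny, nx))
  for (i in seq_len(nz)) {
    s <- slices[[i]]
    # pixel data is row-major: columns vary fastest within a row
    m <- matrix(s$pixels, nrow = nx, ncol = ny)   # (x, y) after fill
    vol[i, , ] <- t(m) * s$slope + s$intercept
  }
  # PixelSpacing is (row spacing, column spacing) = (y, x)
  ct_volume(vol, spacing = c(slice_mm, ps[1], ps[2]),
            origin = c(zpos[1], slices[[1]]$position[2],
                       slices[[1]]$position[1]))
}

# --- minimal explicit-VR little-endian parser -------------------------------

dcm_u16 <- function(raw, at) sum(as.integer(raw[at + 0:1]) * c(1, 256))
dcm_u32 <- function(raw, at)
  sum(as.numeric(raw[at + 0:3]) * c(1, 256, 65536, 16777216))
dcm_str <- function(raw, at, n) {
  b <- raw[at + seq_len(n) - 1]
  b <- b[b != as.raw(0)]             # strip null padding bytes
  trimws(rawToChar(b))
}

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(basename(path), " is not a DICOM part-10 file")
  pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  want <- list()
  transfer_syntax <- NULL
  while (pos + 8 <= length(raw)) {
    group <- dcm_u16(raw, pos); elem <- dcm_u16(raw, pos + 2L)
    vr <- rawToChar(raw[pos + 4:5])
    if (vr %in% long_vrs) {
      len <- dcm_u32(raw, pos + 8L); data_at <- pos + 12L
    } else {
      len <- dcm_u16(raw, pos + 6L); data_at <- pos + 8L
    }
    tag <- sprintf("%04x,%04x", group, elem)
    if (tag == "0002,0010") transfer_syntax <- dcm_str(raw, data_at, len)
    if (group > 2L && !is.null(transfer_syntax) &&
        transfer_syntax != "1.2.840.10008.1.2.1")
      stop(basename(path), ": unsupported transfer syntax ", transfer_syntax,
           " (only explicit-VR little-endian uncompressed is supported)")
    if (tag %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0103")) {
      want[[tag]] <- dcm_u16(raw, data_at)
    } else if (tag %in% c("0028,0030", "0020,0032", "0020,0037",
                          "0028,1052", "0028,1053", "0018,0050")) {
      want[[tag]] <- as.numeric(strsplit(dcm_str(raw, data_at, len),
                                         "\\\\")[[1]])
    } else if (tag == "7fe0,0010") {
      want[[tag]] <- raw[data_at + seq_len(len) - 1]
      break
    }
    pos <- data_at + len
  }
  need <- function(tag, what) {
    if (is.null(want[[tag]]))
      stop(basename(path), ": missing required DICOM attribute ", what,
           " (", tag, ")")
    want[[tag]]
  }
  bits <- need("0028,0100", "BitsAllocated")
  if (bits != 16L)
    stop(basename(path), ": only 16-bit pixel data is supported")
  signed <- identical(want[["0028,0103"]], 1)
  px_raw <- need("7fe0,0010", "PixelData")
  pixels <- readBin(px_raw, "integer", n = length(px_raw) / 2L, size = 2L,
                    signed = signed, endian = "little")
  if (!signed) pixels[pixels < 0] <- pixels[pixels < 0] + 65536L
  ps <- want[["0028,0030"]]
  if (is.null(ps) || length(ps) != 2L || any(!is.finite(ps)) || any(ps <= 0))
    stop(basename(path),
         ": PixelSpacing missing or invalid; refusing to assume 1 mm")
  list(rows = need("0028,0010", "Rows"),
       cols = need("0028,0011", "Columns"),
       pixel_spacing = ps,
       position = need("0020,0032", "ImagePositionPatient"),
       orientation = need("0020,0037", "ImageOrientationPatient"),
       slope = if (is.null(want[["0028,1053"]])) 1 else want[["0028,1053"]],
       intercept = if (is.null(want[["0028,1052"]])) 0
                   else want[["0028,1052"]],
       slice_thickness = if (is.null(want[["0018,0050"]])) NA_real_
                         else want[["0018,0050"]],
       pixels = pixels)
}
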