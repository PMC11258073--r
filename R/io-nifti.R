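#' Read and write volumes and label masks
#'
#' `read_volume()` accepts a NIfTI-1 file (`.nii` / `.nii.gz`) or a
#' directory containing a DICOM series (see [read_dicom_series()]).
#' `read_mask()` reads a NIfTI label volume and validates its codes.
#' NIfTI volumes are written with a float64 datatype so a write/read
#' round trip preserves HU values bit-exactly; masks use uint8.
#'
#' Spacing must be present and strictly positive in the header; a missing
#' or zero pixdim is an error, never silently assumed to be 1 mm. Only
#' axis-aligned orientations are supported; inputs whose xform carries
#' off-diagonal rotation terms are rejected.
#'
#' On disk NIfTI uses (x, y, z) axis order; in memory this package uses
#' (z, y, x). The readers and writers transpose accordingly.
#'
#' @param path File path (or directory, for a DICOM series).
#' @return `read_volume()` a `ct_volume`; `read_mask()` a `label_mask`.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  spacing_xyz <- attr(img, "pixdim")[1:3]
  if (length(spacing_xyz) != 3L || any(!is.finite(spacing_xyz)) ||
      any(spacing_xyz <= 0))
    stop("NIfTI header of ", path,
         " has missing or non-positive voxel spacing; refusing to assume 1 mm")
  check_axis_aligned(img, path)
  hdr <- RNifti::niftiHeader(img)
  origin_xyz <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
  if (any(!is.finite(origin_xyz))) origin_xyz <- c(0, 0, 0)
  ct_volume(aperm(as.array(img), c(3, 2, 1)),
            spacing = rev(spacing_xyz), origin = rev(origin_xyz))
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  label_mask(round(vol$values), vol$spacing, vol$origin)
}

#' @rdname read_volume
#' @param x A `ct_volume` or `label_mask` to write.
#' @export
write_volume <- function(x, path) {
  is_mask <- inherits(x, "label_mask")
  arr <- aperm(if (is_mask) x$labels else x$values, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  attr(img, "pixdim") <- rev(x$spacing)
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "double")
  invisible(path)
}

check_axis_aligned <- function(img, path) {
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(xf, "try-error") || is.null(xf)) return(invisible(TRUE))
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-3 * max(abs(diag(rot)), 1))
    stop("NIfTI ", path, " is not axis-aligned; reorient before reading")
  invisible(TRUE)
}
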