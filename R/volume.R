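#' CT volume and label-mask containers
#'
#' A `ct_volume` is a 3D scalar field in Hounsfield units (HU) with voxel
#' spacing metadata; a `label_mask` is its categorical companion. Arrays use
#' axis order (z, y, x) with z the axial slice index, 1-based indices, and
#' voxel-center coordinates; `spacing` is mm per voxel along (z, y, x).
#'
#' @param values 3D numeric array, HU.
#' @param spacing numeric length-3, mm per voxel along (z, y, x); all > 0.
#' @param origin numeric length-3, physical offset in mm of voxel (1,1,1).
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (z, y, x) in mm")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @rdname ct_volume
#' @param labels 3D integer array with values in `label_codes`.
#' @export
label_mask <- function(labels, spacing, origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array (z, y, x)")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(label_codes))
  if (length(bad))
    stop("label mask contains codes outside {0,1,2,3,255}: ",
         paste(bad, collapse = ", "))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (z, y, x) in mm")
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "label_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels (z,y,x), spacing %s mm, range [%.1f, %.1f] HU\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(as.vector(x$labels), levels = unname(label_codes),
                      labels = names(label_codes)))
  cat(sprintf("<label_mask> %s voxels (z,y,x), spacing %s mm\n",
              paste(dim(x$labels), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = ", ")))
  print(tab)
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

#' @export
dim.label_mask <- function(x) dim(x$labels)

stopifnot_same_grid <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$labels)))
    stop("volume and mask shapes differ: ",
         paste(dim(volume$values), collapse = "x"), " vs ",
         paste(dim(mask$labels), collapse = "x"))
  if (max(abs(volume$spacing - mask$spacing)) > 1e-6)
    stop("volume and mask spacings differ")
  invisible(TRUE)
}

binary_class_mask <- function(mask, class) {
  code <- if (is.character(class)) label_codes[[class]] else as.integer(class)
  mask$labels == code
}
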