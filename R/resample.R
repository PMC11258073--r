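#' Resample a volume or label mask to a target voxel spacing
#'
#' Images are interpolated trilinearly; label masks use nearest-neighbour so
#' no new codes (including the 255 ignore label) can appear. The output
#' shape along each axis is `round(extent_mm / target_spacing)` with R's
#' round-half-to-even rule, which preserves the physical extent to within
#' one voxel. Resampling to the input's own spacing short-circuits to an
#' identity copy.
#'
#' Voxel centers sit at `(i - 0.5) * spacing` mm, so the mapping aligns the
#' physical edges of the two grids; samples beyond the input's outermost
#' voxel centers clamp to the edge value.
#'
#' @param x A `ct_volume` or `label_mask`.
#' @param target_spacing numeric length-3, mm per voxel (z, y, x);
#'   the working grid default used throughout the pipeline is
#'   `c(0.9, 0.66, 0.66)` with 0.9 mm on the axial (z) axis.
#' @return An object of the same class as `x` on the target grid.
#' @export
resample <- function(x, target_spacing = c(0.9, 0.66, 0.66)) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0) ||
      any(!is.finite(target_spacing)))
    stop("`target_spacing` must be three positive values (z, y, x)")
  is_mask <- inherits(x, "label_mask")
  if (!is_mask && !inherits(x, "ct_volume"))
    stop("`x` must be a ct_volume or label_mask")
  arr <- if (is_mask) x$labels else x$values
  if (!is_mask && any(!is.finite(arr)))
    stop("input volume contains non-finite values")
  if (max(abs(x$spacing - target_spacing)) < 1e-9) return(x)

  for (ax in 1:3) {
    arr <- interp_first_axis(arr, x$spacing[ax], target_spacing[ax],
                             nearest = is_mask)
    arr <- aperm(arr, c(2, 3, 1))
  }
  if (is_mask) {
    storage.mode(arr) <- "integer"
    label_mask(arr, target_spacing, x$origin)
  } else {
    ct_volume(arr, target_spacing, x$origin)
  }
}

# Interpolate along the first array axis onto a grid with the requested
# spacing; recycling of a length-n vector down the first dimension does the
# per-slab weighting without any explicit loop.
interp_first_axis <- function(arr, sp_in, sp_out, nearest) {
  n_in <- dim(arr)[1]
  n_out <- max(1L, as.integer(round(n_in * sp_in / sp_out)))
  src <- ((seq_len(n_out) - 0.5) * sp_out) / sp_in + 0.5
  src <- pmin(pmax(src, 1), n_in)
  if (nearest) {
    i <- pmin(pmax(as.integer(floor(src + 0.5)), 1L), n_in)
    return(arr[i, , , drop = FALSE])
  }
  if (n_in == 1L) {
    return(arr[rep(1L, n_out), , , drop = FALSE])
  }
  i0 <- pmin(as.integer(floor(src)), n_in - 1L)
  t <- src - i0
  arr[i0, , , drop = FALSE] * (1 - t) + arr[i0 + 1L, , , drop = FALSE] * t
}
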