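#' Postprocess a predicted label mask
#'
#' For each foreground class, in fixed order (aorta, LM, RCA): keep only
#' the largest 26-connected component, then fill enclosed cavities —
#' background regions (6-connected complement) that do not reach the
#' volume border gain the class label. Size ties between components keep
#' the component whose minimum (z, y, x) index is lexicographically
#' smallest. The operation is idempotent.
#'
#' @param mask a `label_mask`.
#' @return The cleaned `label_mask` (empty classes stay empty).
#' @export
postprocess <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  labels <- mask$labels
  d <- dim(labels)
  for (cls in c("aorta", "lm", "rca")) {
    code <- label_codes[[cls]]
    cls_mask <- labels == code
    if (!any(cls_mask)) next
    keep <- largest_component(cls_mask)
    labels[cls_mask & !keep] <- label_codes[["background"]]
    filled <- fill_holes(keep)
    labels[filled & !keep] <- code
  }
  label_mask(labels, mask$spacing, mask$origin)
}

largest_component <- function(m) {
  d <- dim(m)
  cc <- cpp_label_cc(array(as.integer(m), dim = d), d, 26L)
  sizes <- cc$sizes
  if (length(sizes) == 1L) return(cc$labels == 1L)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break on the lexicographically smallest minimum (z, y, x) index
    mins <- t(vapply(best, function(id) {
      co <- which(cc$labels == id, arr.ind = TRUE)
      co[order(co[, 1], co[, 2], co[, 3])[1], ]
    }, numeric(3)))
    best <- best[order(mins[, 1], mins[, 2], mins[, 3])[1]]
  }
  cc$labels == best
}

fill_holes <- function(m) {
  d <- dim(m)
  bg <- cpp_label_cc(array(as.integer(!m), dim = d), d, 6L)
  if (!length(bg$sizes)) return(m)
  border_ids <- unique(c(bg$labels[c(1, d[1]), , ],
                         bg$labels[, c(1, d[2]), ],
                         bg$labels[, , c(1, d[3])]))
  border_ids <- border_ids[border_ids > 0L]
  m | (bg$labels > 0L & !(bg$labels %in% border_ids))
}

#' Prepare annotation masks for training
#'
#' Coronary-artery (LM/RCA) voxels whose Euclidean distance from the aorta
#' segmentation exceeds `cutoff_mm` are set to the ignore label, and the
#' one-voxel inner and outer boundary shell of every class is ignored as
#' well: voxels at segmentation edges are neither well-defined nor precise
#' enough to supervise on. The aorta interior is left unchanged.
#'
#' @param mask `label_mask` containing an aorta class.
#' @param cutoff_mm distance cutoff in mm (default 20); `Inf` disables the
#'   distance rule so only boundary shells are ignored.
#' @return A `label_mask` with ignore labels (code 255) applied.
#' @export
preprocess_labels <- function(mask, cutoff_mm = 20) {
  stopifnot(inherits(mask, "label_mask"))
  labels <- mask$labels
  d <- dim(labels)
  aorta <- labels == label_codes[["aorta"]]
  if (!any(aorta)) stop("mask contains no aorta voxels")
  out <- labels

  if (is.finite(cutoff_mm)) {
    dist2 <- cpp_edt_sq(array(as.integer(!aorta), dim = d), d,
                        mask$spacing)
    far <- dist2 > cutoff_mm^2
    artery <- labels == label_codes[["lm"]] | labels == label_codes[["rca"]]
    out[artery & far] <- label_codes[["ignore"]]
  }
  for (cls in c("aorta", "lm", "rca")) {
    m <- labels == label_codes[[cls]]
    if (!any(m)) next
    shell <- boundary_shell(m)
    out[shell] <- label_codes[["ignore"]]
  }
  label_mask(out, mask$spacing, mask$origin)
}

# inner + outer 1-voxel shell of a binary mask (6-neighbourhood)
boundary_shell <- function(m) {
  d <- dim(m)
  shift <- function(arr, ax, by) {
    idx <- pmin(pmax(seq_len(d[ax]) + by, 1L), d[ax])
    switch(ax, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
           arr[, , idx, drop = FALSE])
  }
  touch_other <- array(FALSE, dim = d)
  for (ax in 1:3) for (by in c(-1L, 1L))
    touch_other <- touch_other | (shift(m, ax, by) != m)
  touch_other
}

#' Dice overlap coefficient between two masks for one class
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty for the class.
#'
#' @param pred,truth `label_mask`s of identical shape.
#' @param class class name (`"aorta"`, `"lm"`, `"rca"`) or integer code.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(pred, truth, class = "aorta") {
  if (!identical(dim(pred$labels), dim(truth$labels)))
    stop("mask shapes differ: ", paste(dim(pred$labels), collapse = "x"),
         " vs ", paste(dim(truth$labels), collapse = "x"))
  a <- binary_class_mask(pred, class)
  b <- binary_class_mask(truth, class)
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1)
  2 * sum(a & b) / denom
}
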