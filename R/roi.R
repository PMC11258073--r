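#' Locate the LM-aorta contact point
#'
#' The left main (LM) segmentation is dilated by one voxel in all
#' directions within each axial plane (3x3 structuring element, no
#' through-slice dilation); the dilated voxels that overlap the original
#' aorta segmentation form the contact-point set. The measurement center
#' slice is the median axial index of the contact voxels, with half-integer
#' medians rounded toward the lower index.
#'
#' @param mask A `label_mask` containing aorta and LM classes.
#' @return List with `contact` (matrix of (z, y, x) voxel indices),
#'   `center_slice` and `n_contact`.
#' @section Errors: if no dilated LM voxel touches the aorta, a condition of
#'   class `contact_not_found` is signalled — the anatomy-anomaly failure
#'   mode (for example an LM originating from the RCA), which callers record
#'   rather than crash on.
#' @export
find_contact_point <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  aorta <- binary_class_mask(mask, "aorta")
  lm <- binary_class_mask(mask, "lm")
  if (!any(aorta)) stop("mask contains no aorta voxels")
  if (!any(lm)) {
    stop(errorCondition("no LM voxels in mask; cannot locate the LM ostium",
                        class = "contact_not_found"))
  }
  dil <- dilate_inplane_3x3(lm)
  contact <- dil & aorta
  if (!any(contact)) {
    stop(errorCondition(
      "dilated LM does not touch the aorta segmentation; LM ostium not found",
      class = "contact_not_found"))
  }
  coords <- which(contact, arr.ind = TRUE)
  colnames(coords) <- c("z", "y", "x")
  list(contact = coords,
       center_slice = as.integer(floor(median(coords[, "z"]))),
       n_contact = nrow(coords))
}

# one-voxel 8-neighbourhood dilation within each axial (y, x) plane
dilate_inplane_3x3 <- function(m) {
  out <- m
  d <- dim(m)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    xs <- pmin(pmax(seq_len(d[3]) + dx, 1L), d[3])
    # clamped indexing duplicates the border row/column, which can only add
    # voxels already present there; dilation semantics are preserved
    out <- out | m[, ys, xs, drop = FALSE]
  }
  out
}

#' Radially shrink one axial aorta cross-section
#'
#' The slice's equivalent-circle radius is `sqrt(area_mm2 / pi)`;
#' voxels whose distance to the mask boundary is at least `fraction * r`
#' are retained. Distance is the Euclidean distance (in mm, respecting
#' anisotropic in-plane spacing) to the nearest background voxel center,
#' minus half the mean in-plane spacing so that it measures to the
#' inside/outside midline rather than to the neighbouring center.
#'
#' @param slice_mask 2D logical (y, x) aorta cross-section.
#' @param fraction fraction of the equivalent radius to shave off;
#'   default 1/3.
#' @param spacing_yx in-plane mm per voxel (y, x).
#' @return 2D logical mask of retained voxels (empty in, empty out).
#' @export
shrink_slice_mask <- function(slice_mask, fraction = 1/3,
                              spacing_yx = c(0.66, 0.66)) {
  stopifnot(is.logical(slice_mask), length(dim(slice_mask)) == 2L)
  if (!any(slice_mask)) return(slice_mask & FALSE)
  area_mm2 <- sum(slice_mask) * prod(spacing_yx)
  r <- sqrt(area_mm2 / pi)
  d <- dim(slice_mask)
  edt2 <- cpp_edt_sq(array(as.integer(slice_mask), dim = c(d, 1L)),
                     c(d, 1L), c(spacing_yx, 1))
  dist_mm <- sqrt(edt2[, , 1]) - mean(spacing_yx) / 2
  slice_mask & (dist_mm >= fraction * r)
}

#' Build the seven-slice measurement zone at the LM level
#'
#' The zone is the union, over axial slices `center_slice - half_width` to
#' `center_slice + half_width` (default 3, i.e. seven slices), of the
#' radially shrunk aorta cross-sections. Slices falling outside the volume
#' are dropped with a warning and noted in the returned provenance, so a
#' zone near the volume edge may hold fewer than seven slices.
#'
#' @param mask `label_mask` with aorta and LM classes.
#' @param fraction radial shrink fraction per slice (default 1/3).
#' @param half_width slices added above and below the center (default 3).
#' @return A `measurement_zone`: `center_slice`, `slices` (axial indices),
#'   `slice_masks` (2D logical per slice), `n_voxels`, `warnings`.
#' @section Errors: `zone_empty` if every candidate slice shrinks to
#'   nothing; `contact_not_found` propagated from the contact search.
#' @export
build_zone <- function(mask, fraction = 1/3, half_width = 3L) {
  cp <- find_contact_point(mask)
  nz <- dim(mask$labels)[1]
  wanted <- (cp$center_slice - half_width):(cp$center_slice + half_width)
  slices <- wanted[wanted >= 1L & wanted <= nz]
  warnings <- character()
  if (length(slices) < length(wanted)) {
    w <- sprintf("measurement zone clipped at volume edge: %d of %d slices kept",
                 length(slices), length(wanted))
    warning(w)
    warnings <- w
  }
  aorta <- binary_class_mask(mask, "aorta")
  slice_masks <- lapply(slices, function(z)
    shrink_slice_mask(aorta[z, , ], fraction, mask$spacing[2:3]))
  n_per_slice <- vapply(slice_masks, sum, 0L)
  keep <- n_per_slice > 0L
  if (!any(keep)) {
    stop(errorCondition("all candidate slices shrink to an empty mask",
                        class = "zone_empty"))
  }
  structure(list(center_slice = cp$center_slice,
                 slices = slices[keep],
                 slice_masks = slice_masks[keep],
                 n_voxels = sum(n_per_slice),
                 n_per_slice = n_per_slice[keep],
                 contact = cp$contact,
                 warnings = warnings),
            class = "measurement_zone")
}

#' @export
print.measurement_zone <- function(x, ...) {
  cat(sprintf("<measurement_zone> center slice %d, %d slices (%s), %d voxels\n",
              x$center_slice, length(x$slices),
              paste(range(x$slices), collapse = "-"), x$n_voxels))
  invisible(x)
}

zone_values <- function(volume, zone) {
  unlist(lapply(seq_along(zone$slices), function(i)
    volume$values[zone$slices[i], , ][zone$slice_masks[[i]]]),
    use.names = FALSE)
}

#' Attenuation, noise and SNR within a voxel set
#'
#' Attenuation is the mean HU over the zone; noise is the sample standard
#' deviation (n - 1 denominator); SNR is their quotient (dimensionless).
#' A zero-variance zone yields `snr = NA` (explicitly undefined, never
#' infinite).
#'
#' @param volume `ct_volume` on the same grid as the zone's mask.
#' @param zone a `measurement_zone`, or a numeric vector of HU values.
#' @return A `noise_measurement`: `attenuation`, `noise`, `snr`,
#'   `n_voxels`, `center_slice`.
#' @export
measure <- function(volume, zone) {
  if (inherits(zone, "measurement_zone")) {
    vals <- zone_values(volume, zone)
    cs <- zone$center_slice
  } else {
    vals <- as.numeric(zone)
    cs <- NA_integer_
  }
  if (!length(vals)) stop("measurement zone is empty")
  att <- mean(vals)
  noise <- if (length(vals) > 1L) sd(vals) else 0
  structure(list(attenuation = att, noise = noise,
                 snr = if (noise > 0) att / noise else NA_real_,
                 n_voxels = length(vals), center_slice = cs),
            class = "noise_measurement")
}

#' @export
print.noise_measurement <- function(x, ...) {
  cat(sprintf("<noise_measurement> attenuation %.1f HU, noise %.2f HU, SNR %s (n = %d voxels)\n",
              x$attenuation, x$noise,
              if (is.na(x$snr)) "undefined" else sprintf("%.2f", x$snr),
              x$n_voxels))
  invisible(x)
}

#' Measure a manual-style circular ROI
#'
#' Emulates the reader's comparator measurement: a single-slice circular
#' region of interest of the given diameter (default 15 mm) centered in the
#' aortic root at the LM level. Voxel centers within `diameter / 2` mm of
#' the center voxel's center belong to the ROI.
#'
#' @param volume `ct_volume`.
#' @param center integer (z, y, x) voxel index of the ROI center.
#' @param diameter_mm ROI diameter in mm; default 15.
#' @return A `noise_measurement`.
#' @export
measure_manual_roi <- function(volume, center, diameter_mm = 15) {
  stopifnot(diameter_mm > 0, length(center) == 3L)
  d <- dim(volume$values)
  if (any(center < 1L) || any(center > d))
    stop("ROI center lies outside the volume")
  r <- diameter_mm / 2
  sy <- volume$spacing[2]; sx <- volume$spacing[3]
  yc <- (center[2] - 1) * sy; xc <- (center[3] - 1) * sx
  if (yc - r < -sy / 2 || yc + r > (d[2] - 1) * sy + sy / 2 ||
      xc - r < -sx / 2 || xc + r > (d[3] - 1) * sx + sx / 2)
    stop("15 mm ROI extends outside the volume at this center")
  ymm <- (seq_len(d[2]) - 1) * sy
  xmm <- (seq_len(d[3]) - 1) * sx
  disc <- outer((ymm - yc)^2, (xmm - xc)^2, `+`) <= r^2
  m <- measure(NULL, volume$values[center[1], , ][disc])
  m$center_slice <- as.integer(center[1])
  m
}

#' Run the full measurement pipeline on one study
#'
#' End to end: (optionally) resample to the model's working grid, segment,
#' postprocess, locate the LM contact point, build the zone and measure.
#' A study whose LM ostium cannot be found is returned with status
#' `failed:ContactNotFound` rather than raising — failed studies are
#' recorded, never silently dropped.
#'
#' @param volume `ct_volume` (native or working grid).
#' @param mask ground-truth or precomputed `label_mask` (skips inference).
#' @param model a `trained_unet` used to segment when `mask` is `NULL`.
#' @param study_id identifier attached to the record and to error messages.
#' @param shrink_fraction,zone_half_width zone geometry; defaults 1/3 and 3.
#' @return A one-row data.frame: study_id, attenuation, noise, snr,
#'   n_voxels, center_slice, status.
#' @export
run_study <- function(volume, mask = NULL, model = NULL,
                      study_id = "study", shrink_fraction = 1/3,
                      zone_half_width = 3L) {
  rec <- data.frame(study_id = study_id, attenuation = NA_real_,
                    noise = NA_real_, snr = NA_real_,
                    n_voxels = NA_integer_, center_slice = NA_integer_,
                    status = "ok", stringsAsFactors = FALSE)
  res <- tryCatch({
    if (is.null(mask)) {
      if (is.null(model)) stop("either a mask or a model is required")
      if (max(abs(volume$spacing - model$config$spacing)) > 1e-6)
        volume <- resample(volume, model$config$spacing)
      mask <- postprocess(sliding_window_infer(model, volume))
    }
    stopifnot_same_grid(volume, mask)
    zone <- build_zone(mask, fraction = shrink_fraction,
                       half_width = zone_half_width)
    measure(volume, zone)
  },
  contact_not_found = function(e) "failed:ContactNotFound",
  zone_empty = function(e) "failed:ZoneEmpty")
  if (is.character(res)) {
    rec$status <- res
  } else {
    rec$attenuation <- res$attenuation
    rec$noise <- res$noise
    rec$snr <- res$snr
    rec$n_voxels <- res$n_voxels
    rec$center_slice <- res$center_slice
  }
  rec
}

#' Measure every phantom of a cohort
#'
#' @param phantoms list of `ct_phantom`.
#' @param use_truth_masks measure on the generator's ground-truth masks
#'   (default) instead of running a segmentation model.
#' @param model optional `trained_unet` when `use_truth_masks = FALSE`.
#' @param ... passed to [run_study()].
#' @return data.frame of study records joined with the cohort manifest.
#' @export
run_cohort <- function(phantoms, use_truth_masks = TRUE, model = NULL, ...) {
  man <- cohort_manifest(phantoms)
  recs <- lapply(seq_along(phantoms), function(i) {
    p <- phantoms[[i]]
    run_study(p$volume,
              mask = if (use_truth_masks) p$labels else NULL,
              model = model, study_id = man$study_id[i], ...)
  })
  merge(do.call(rbind, recs), man, by = "study_id", sort = TRUE)
}
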