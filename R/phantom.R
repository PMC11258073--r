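#' Specification of a synthetic CCTA phantom
#'
#' The phantom emulates the structures the measurement pipeline depends on:
#' a contrast-filled aortic root as a vertical tube spanning the volume, a
#' left main coronary artery (LM) as a horizontal tube emanating from the
#' aortic wall, a right coronary artery (RCA) tube on the opposite side at
#' a different height, a soft-tissue background, and i.i.d. per-voxel
#' Gaussian noise of known standard deviation. Labels record the noise-free
#' geometry exactly, so every downstream stage has exact ground truth.
#'
#' Geometry is defined analytically in mm (voxel centers inside the signed
#' distance of each tube), then voxelized at `spacing`; boundaries are hard
#' by default, with optional Gaussian edge softening via `edge_blur_sigma`.
#'
#' @param shape integer length-3, voxel counts (z, y, x).
#' @param spacing mm per voxel (z, y, x); default matches the pipeline's
#'   working grid `c(0.9, 0.66, 0.66)`.
#' @param aorta_attenuation,background_attenuation HU of the contrast-filled
#'   lumen (~450-600 in practice) and of the soft-tissue background.
#' @param noise_sd standard deviation (HU) of the additive Gaussian noise;
#'   `>= 0`.
#' @param aorta_radius,lm_radius,rca_radius tube radii in mm; all positive,
#'   `lm_radius < aorta_radius`.
#' @param lm_z_position,rca_z_position height of the LM / RCA tube axis as a
#'   fraction of the volume's z extent.
#' @param edge_blur_sigma optional Gaussian blur (mm) applied to the
#'   noise-free image at tissue boundaries; 0 (default) keeps boundaries
#'   exact for testing.
#' @param seed RNG seed making the phantom fully deterministic.
#' @param quality_label optional diagnostic quality category (one of
#'   `quality_levels`).
#' @param excluded_fraction optional fraction in `[0, 1]` of coronary tree
#'   length excluded for image-quality reasons.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(48, 80, 80),
                         spacing = c(0.9, 0.66, 0.66),
                         aorta_attenuation = 500,
                         background_attenuation = 50,
                         noise_sd = 35,
                         aorta_radius = 15,
                         lm_radius = 2.25,
                         rca_radius = 1.75,
                         lm_z_position = 0.6,
                         rca_z_position = 0.35,
                         edge_blur_sigma = 0,
                         seed = 1L,
                         quality_label = NULL,
                         excluded_fraction = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing) == 3L, all(spacing > 0))
  if (!(aorta_radius > 0 && lm_radius > 0 && rca_radius > 0))
    stop("all radii must be > 0")
  if (lm_radius >= aorta_radius)
    stop("lm_radius must be smaller than aorta_radius")
  if (!(noise_sd >= 0)) stop("noise_sd must be >= 0")
  if (!is.null(quality_label))
    quality_label <- match.arg(quality_label, quality_levels)
  if (!is.null(excluded_fraction) &&
      (excluded_fraction < 0 || excluded_fraction > 1))
    stop("excluded_fraction must lie in [0, 1]")

  # the aorta tube plus a 5-voxel margin must fit in-plane, and the LM/RCA
  # tubes must fit along z; fail loudly naming the offending axis
  margin <- 5
  for (ax in 2:3) {
    half_extent <- (shape[ax] - 1) / 2 * spacing[ax]
    if (aorta_radius + margin * spacing[ax] > half_extent)
      stop(sprintf(
        "aorta radius %.1f mm plus a %d-voxel margin does not fit along the %s axis (%d voxels at %.2f mm)",
        aorta_radius, margin, c("z", "y", "x")[ax], shape[ax], spacing[ax]))
  }
  for (nm in c("lm", "rca")) {
    frac <- if (nm == "lm") lm_z_position else rca_z_position
    r <- if (nm == "lm") lm_radius else rca_radius
    zc <- frac * (shape[1] - 1) * spacing[1]
    if (zc - r < 0 || zc + r > (shape[1] - 1) * spacing[1])
      stop(sprintf("%s tube at z fraction %.2f does not fit along the z axis",
                   toupper(nm), frac))
  }
  structure(list(shape = shape, spacing = spacing,
                 aorta_attenuation = aorta_attenuation,
                 background_attenuation = background_attenuation,
                 noise_sd = noise_sd, aorta_radius = aorta_radius,
                 lm_radius = lm_radius, rca_radius = rca_radius,
                 lm_z_position = lm_z_position,
                 rca_z_position = rca_z_position,
                 edge_blur_sigma = edge_blur_sigma,
                 seed = as.integer(seed),
                 quality_label = quality_label,
                 excluded_fraction = excluded_fraction),
            class = "phantom_spec")
}

#' Generate a synthetic CCTA phantom
#'
#' Voxel values are `class attenuation + N(0, noise_sd)`; labels are the
#' noise-free geometry. Output is bit-identical for identical spec + seed.
#' The LM tube is guaranteed to touch the aortic wall (its axis starts at
#' the aorta center; voxels inside the aorta keep the aorta label), so the
#' contact-point search downstream always has a target.
#'
#' @param spec A [phantom_spec()].
#' @return A `ct_phantom`: list with `volume` (`ct_volume`), `labels`
#'   (`label_mask`), `true_attenuation`, `true_noise_sd`,
#'   `contact_slice_true` (axial index of the LM axis) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  sz <- spec$spacing[1]; sy <- spec$spacing[2]; sx <- spec$spacing[3]
  zmm <- (seq_len(nz) - 1) * sz
  ymm <- (seq_len(ny) - 1) * sy
  xmm <- (seq_len(nx) - 1) * sx
  cy <- ymm[ny] / 2; cx <- xmm[nx] / 2

  # aorta: vertical tube spanning the whole z extent
  d2_inplane <- outer((ymm - cy)^2, (xmm - cx)^2, `+`)     # (y, x)
  aorta <- aperm(array(d2_inplane <= spec$aorta_radius^2,
                       dim = c(ny, nx, nz)), c(3, 1, 2))

  # LM: horizontal tube along +x at height lm_z_position; RCA along -x
  tube_x <- function(z_frac, radius, positive_x) {
    zc <- z_frac * zmm[nz]
    cross <- outer((zmm - zc)^2, (ymm - cy)^2, `+`) <= radius^2  # (z, y)
    m <- array(cross, dim = c(nz, ny, nx))
    keep <- if (positive_x) xmm >= cx else xmm <= cx
    m[, , !keep] <- FALSE
    m
  }
  lm <- tube_x(spec$lm_z_position, spec$lm_radius, TRUE)
  rca <- tube_x(spec$rca_z_position, spec$rca_radius, FALSE)

  labels <- array(label_codes[["background"]], dim = spec$shape)
  labels[rca] <- label_codes[["rca"]]
  labels[lm] <- label_codes[["lm"]]
  labels[aorta] <- label_codes[["aorta"]]

  clean <- array(spec$background_attenuation, dim = spec$shape)
  clean[labels != 0L] <- spec$aorta_attenuation
  if (spec$edge_blur_sigma > 0)
    clean <- gaussian_blur3(clean, spec$spacing, spec$edge_blur_sigma)

  values <- clean
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    values <- values + array(rnorm(length(clean), 0, spec$noise_sd),
                             dim = spec$shape)
  }

  structure(list(
    volume = ct_volume(values, spec$spacing),
    labels = label_mask(labels, spec$spacing),
    true_attenuation = spec$aorta_attenuation,
    true_noise_sd = spec$noise_sd,
    contact_slice_true = round(spec$lm_z_position * (nz - 1)) + 1L,
    spec = spec), class = "ct_phantom")
}

# separable Gaussian blur, sigma in mm, reflective edges
gaussian_blur3 <- function(arr, spacing, sigma) {
  for (ax in 1:3) {
    sd_vox <- sigma / spacing[ax]
    if (sd_vox > 1e-3) {
      half <- max(1L, ceiling(3 * sd_vox))
      k <- exp(-0.5 * ((-half:half) / sd_vox)^2); k <- k / sum(k)
      n <- dim(arr)[1]
      idx <- outer(seq_len(n), -half:half, `+`)
      idx <- pmin(pmax(idx, 1L), n)          # replicate edges
      acc <- array(0, dim = dim(arr))
      for (j in seq_along(k))
        acc <- acc + arr[idx[, j], , , drop = FALSE] * k[j]
      arr <- acc
    }
    arr <- aperm(arr, c(2, 3, 1))
  }
  arr
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("<ct_phantom> %s voxels, signal %.0f HU, noise SD %.1f HU%s\n",
              paste(dim(x$volume), collapse = "x"), x$true_attenuation,
              x$true_noise_sd,
              if (!is.null(x$spec$quality_label))
                paste0(", quality ", x$spec$quality_label) else ""))
  invisible(x)
}
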