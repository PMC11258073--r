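#' Default cohort noise / attenuation distributions per quality category
#'
#' Label-conditional medians come from published group summaries of a large
#' single-scanner CCTA cohort (noise 33.1 / 36.1 / 42.1 HU and attenuation
#' 533.7 / 502.0 / 466.0 HU for fully diagnostic, diagnostic with excluded
#' parts, and non-diagnostic studies); spreads are the corresponding IQRs
#' converted to Gaussian SDs (IQR / 1.349). These are emulation defaults,
#' not ground truth: the source reports no distributional form.
#'
#' @format Named list, one `(median, spread)` pair per quality label.
#' @export
default_noise_by_label <- list(
  fully_diagnostic = c(median = 33.1, spread = (37.9 - 29.8) / 1.349),
  excluded_parts   = c(median = 36.1, spread = (40.3 - 31.5) / 1.349),
  non_diagnostic   = c(median = 42.1, spread = (47.7 - 35.2) / 1.349))

#' @rdname default_noise_by_label
#' @export
default_attenuation_by_label <- list(
  fully_diagnostic = c(median = 533.7, spread = (581.0 - 484.7) / 1.349),
  excluded_parts   = c(median = 502.0, spread = (552.3 - 465.7) / 1.349),
  non_diagnostic   = c(median = 466.0, spread = (536.3 - 421.4) / 1.349))

#' Generate a cohort of labelled phantoms
#'
#' Each phantom receives a quality label (drawn with probabilities
#' `label_proportions`, default 158/341/29 out of 528 — the group sizes of
#' the emulated evaluation cohort), an injected noise SD drawn from the
#' label-conditional Gaussian in `noise_sd_by_label` (truncated below at
#' 5 HU), and an attenuation drawn from `attenuation_by_label` (truncated
#' at 100 HU). Phantoms in the `excluded_parts` group additionally carry an
#' excluded-vessel fraction with a positive monotone dependence on their
#' injected noise, emulating the weak noise / excluded-length correlation
#' seen in real readings:
#' `fraction = clamp(0.1 + 0.015 (SD - 30) + N(0, 0.15), 0, 1)`.
#'
#' @param n Number of phantoms (>= 1).
#' @param noise_sd_by_label named list with entries for all three
#'   `quality_levels`, each `c(median, spread)` in HU.
#' @param seed integer seed; the cohort (labels, draws, per-phantom seeds)
#'   is fully reproducible.
#' @param attenuation_by_label as `noise_sd_by_label`, for the contrast
#'   attenuation.
#' @param label_proportions sampling weights for the three labels.
#' @param total_vessel_length_mm nominal analysed coronary tree length used
#'   to convert excluded fractions to excluded lengths.
#' @param base_spec a [phantom_spec()] providing the shared geometry.
#' @return List of `ct_phantom`; see [cohort_manifest()] for the tabular
#'   view.
#' @export
generate_cohort <- function(n,
                            noise_sd_by_label = default_noise_by_label,
                            seed = 1L,
                            attenuation_by_label = default_attenuation_by_label,
                            label_proportions = c(158, 341, 29) / 528,
                            total_vessel_length_mm = 400,
                            base_spec = phantom_spec()) {
  if (n < 1) stop("n must be >= 1")
  if (!all(quality_levels %in% names(noise_sd_by_label)))
    stop("noise_sd_by_label must name all three quality labels: ",
         paste(quality_levels, collapse = ", "))
  set.seed(as.integer(seed))
  labels <- sample(quality_levels, n, replace = TRUE,
                   prob = label_proportions)
  draw <- function(map, lab, floor_at) {
    p <- map[[lab]]
    max(floor_at, rnorm(1, p[["median"]], p[["spread"]]))
  }
  phantoms <- vector("list", n)
  seeds <- sample.int(.Machine$integer.max, n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    sd_i <- draw(noise_sd_by_label, lab, 5)
    att_i <- draw(attenuation_by_label, lab, 100)
    excl <- switch(lab,
      fully_diagnostic = 0,
      non_diagnostic = NULL,   # whole study excluded; no partial fraction
      excluded_parts = min(1, max(0, 0.1 + 0.015 * (sd_i - 30) +
                                       rnorm(1, 0, 0.15))))
    spec <- phantom_spec(
      shape = base_spec$shape, spacing = base_spec$spacing,
      aorta_attenuation = att_i,
      background_attenuation = base_spec$background_attenuation,
      noise_sd = sd_i,
      aorta_radius = base_spec$aorta_radius,
      lm_radius = base_spec$lm_radius, rca_radius = base_spec$rca_radius,
      lm_z_position = base_spec$lm_z_position,
      rca_z_position = base_spec$rca_z_position,
      edge_blur_sigma = base_spec$edge_blur_sigma,
      seed = seeds[i], quality_label = lab, excluded_fraction = excl)
    phantoms[[i]] <- generate_phantom(spec)
  }
  phantoms
}

#' Tabulate a phantom cohort
#'
#' @param phantoms list of `ct_phantom` from [generate_cohort()].
#' @param paths optional data.frame of file paths to join (columns
#'   `volume_path`, `mask_path`).
#' @return data.frame with study_id, quality_label, true noise/attenuation
#'   and excluded lengths.
#' @export
cohort_manifest <- function(phantoms, paths = NULL) {
  total_len <- 400
  df <- data.frame(
    study_id = sprintf("study_%04d", seq_along(phantoms)),
    quality_label = vapply(phantoms, function(p)
      p$spec$quality_label %||% NA_character_, ""),
    true_noise_sd = vapply(phantoms, `[[`, 0, "true_noise_sd"),
    true_attenuation = vapply(phantoms, `[[`, 0, "true_attenuation"),
    excluded_fraction = vapply(phantoms, function(p)
      p$spec$excluded_fraction %||% NA_real_, 0),
    stringsAsFactors = FALSE)
  df$total_length_mm <- ifelse(is.na(df$excluded_fraction), NA_real_,
                               total_len)
  df$excluded_length_mm <- df$excluded_fraction * df$total_length_mm
  if (!is.null(paths)) df <- cbind(df, paths)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
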