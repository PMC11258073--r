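test_that("a single in-plane neighbour defines the contact point", {
  m <- blank_mask(c(16L, 16L, 16L))
  m$labels[10, 5, 5] <- 2L        # LM voxel
  m$labels[10, 5, 6] <- 1L        # aorta voxel, in-plane neighbour
  m$labels[3, 12, 12] <- 1L       # distant aorta voxel, different slice
  cp <- find_contact_point(m)
  expect_identical(unname(cp$contact[1, ]), c(10L, 5L, 6L))
  expect_identical(cp$n_contact, 1L)
  expect_identical(cp$center_slice, 10L)
})

test_that("the center slice is the median contact slice, rounded down", {
  m <- blank_mask(c(20L, 10L, 10L))
  for (z in 10:12) {
    m$labels[z, 5, 5] <- 2L
    m$labels[z, 5, 6] <- 1L
  }
  expect_identical(find_contact_point(m)$center_slice, 11L)
  # even number of contact slices: half-integer median rounds down
  m$labels[13, 5, 5] <- 2L
  m$labels[13, 5, 6] <- 1L
  expect_identical(find_contact_point(m)$center_slice, 11L)
})

test_that("dilation is strictly in-plane (no through-slice contact)", {
  m <- blank_mask(c(16L, 16L, 16L))
  m$labels[10, 5, 5] <- 2L
  m$labels[11, 5, 5] <- 1L        # adjacent only through the slice axis
  expect_error(find_contact_point(m), class = "contact_not_found")
})

test_that("an LM far from the aorta raises contact_not_found", {
  m <- blank_mask(c(16L, 16L, 16L))
  m$labels[10, 2:4, 2:4] <- 1L
  m$labels[10, 10:12, 10:12] <- 2L
  expect_error(find_contact_point(m), class = "contact_not_found")
  expect_error(find_contact_point(blank_mask()), "no aorta")
})

test_that("disc shrinking retains the analytic (2/3)^2 area fraction", {
  dd <- 71L
  disc <- outer((1:dd - 36)^2, (1:dd - 36)^2, `+`) <= 30^2
  shr <- shrink_slice_mask(disc, 1/3, c(1, 1))
  ratio <- sum(shr) / sum(disc)
  expect_lt(abs(ratio - (2/3)^2), 0.02)
  # empty in, empty out
  expect_identical(sum(shrink_slice_mask(disc & FALSE, 1/3, c(1, 1))), 0L)
})

test_that("single-voxel slices follow the distance-transform rule", {
  m <- array(FALSE, dim = c(9, 9))
  m[5, 5] <- TRUE
  got <- shrink_slice_mask(m, 1/3, c(0.66, 0.66))
  # brute-force EDT on the 1-voxel mask: distance to nearest background
  # center is one voxel, minus the half-voxel midline correction
  d_mm <- 0.66 - 0.66 / 2
  r <- sqrt(1 * 0.66^2 / pi)
  expect_identical(got[5, 5], d_mm >= r / 3)
})

test_that("shrinking is monotone in the fraction", {
  set.seed(3)
  blob <- matrix(FALSE, 40, 40)
  blob[8:32, 10:30] <- TRUE
  blob[sample(1600, 50)] <- TRUE
  s_small <- shrink_slice_mask(blob, 0.2, c(0.66, 0.66))
  s_large <- shrink_slice_mask(blob, 0.5, c(0.66, 0.66))
  expect_true(all(!s_large | s_small))   # larger fraction => subset
})

test_that("the zone holds seven slices centered on the contact slice", {
  p <- generate_phantom(toy_phantom_spec(seed = 6))
  z <- build_zone(p$labels)
  cs <- find_contact_point(p$labels)$center_slice
  expect_identical(z$slices, (cs - 3L):(cs + 3L))
  expect_length(z$slices, 7L)
  # containment: every zone voxel lies inside the original aorta mask
  aorta <- p$labels$labels == 1L
  for (i in seq_along(z$slices))
    expect_true(all(aorta[z$slices[i], , ][z$slice_masks[[i]]]))
})

test_that("zones at the volume edge are clipped with a warning", {
  p <- generate_phantom(toy_phantom_spec(seed = 6, lm_z_position = 0.08))
  expect_warning(z <- build_zone(p$labels), "clipped")
  expect_lt(length(z$slices), 7L)
  expect_gt(length(z$slices), 0L)
  expect_match(z$warnings, "clipped")
})

test_that("measurement statistics are exact on constructed inputs", {
  vals <- rep(400, 50)
  m <- measure(NULL, vals)
  expect_identical(m$attenuation, 400)
  expect_identical(m$noise, 0)
  expect_true(is.na(m$snr))          # undefined, never infinite
  m2 <- measure(NULL, c(370, 430))
  expect_equal(m2$attenuation, 400)
  expect_equal(m2$noise, sd(c(370, 430)))
  # independent single-pass mean/SD agreement
  set.seed(4)
  v <- rnorm(5000, 450, 35)
  m3 <- measure(NULL, v)
  expect_equal(m3$attenuation, sum(v) / length(v), tolerance = 1e-12)
  expect_equal(m3$noise,
               sqrt((sum(v^2) - sum(v)^2 / length(v)) / (length(v) - 1)),
               tolerance = 1e-9)
})

test_that("phantom measurements recover the injected signal and noise", {
  p <- generate_phantom(phantom_spec(aorta_attenuation = 450,
                                     noise_sd = 35, aorta_radius = 16,
                                     seed = 12))
  z <- build_zone(p$labels)
  expect_gte(z$n_voxels, 5000)
  m <- measure(p$volume, z)
  expect_lt(abs(m$attenuation - 450), 2)
  expect_lt(abs(m$noise - 35), 1.5)
  expect_equal(m$snr, m$attenuation / m$noise)
})

test_that("the manual 15 mm ROI has the analytic voxel count", {
  p <- generate_phantom(phantom_spec(noise_sd = 0))
  d <- dim(p$volume)
  ctr <- c(find_contact_point(p$labels)$center_slice,
           round((d[2] + 1) / 2), round((d[3] + 1) / 2))
  m <- measure_manual_roi(p$volume, ctr, 15)
  expect_lt(abs(m$n_voxels - pi * 7.5^2 / 0.66^2) / (pi * 7.5^2 / 0.66^2),
            0.03)
  expect_identical(m$noise, 0)
  # zero-noise phantom: manual and automatic attenuation agree exactly
  auto <- measure(p$volume, build_zone(p$labels))
  expect_identical(m$attenuation, auto$attenuation)
  # ROI overflowing the volume is refused
  expect_error(measure_manual_roi(p$volume, c(ctr[1], 2, 2), 15),
               "outside")
})

test_that("run_study records contact failures instead of crashing", {
  p <- generate_phantom(toy_phantom_spec(seed = 13))
  nolm <- p$labels
  nolm$labels[nolm$labels == 2L] <- 0L
  rec <- run_study(p$volume, mask = nolm, study_id = "anomaly")
  expect_identical(rec$status, "failed:ContactNotFound")
  expect_true(is.na(rec$noise))

  ok <- run_study(p$volume, mask = p$labels, study_id = "fine")
  expect_identical(ok$status, "ok")
  expect_gt(ok$n_voxels, 0)
})

test_that("a phantom cohort measures end to end without failures", {
  coh <- generate_cohort(20, seed = 31, base_spec = toy_phantom_spec())
  recs <- run_cohort(coh)
  expect_identical(nrow(recs), 20L)
  expect_true(all(recs$status == "ok"))
  expect_true(all(abs(recs$snr - recs$attenuation / recs$noise) < 1e-6))
})
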