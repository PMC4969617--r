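test_that("centroid finds a single bright pixel exactly", {
  img <- matrix(0, 40, 40)
  img[20, 10] <- 50                # row = y, col = x
  frame <- microscopy_frame(img, reflection = img, pixel_size_um = 0.1)
  expect_equal(locate_center(frame), c(x = 10, y = 20))
})

test_that("centroid resolves a sub-pixel Gaussian center to < 0.05 px", {
  frame <- gaussian_spot_frame(center = c(32.5, 17.25))
  ctr <- locate_center(frame)
  expect_lt(abs(ctr[["x"]] - 32.5), 0.05)
  expect_lt(abs(ctr[["y"]] - 17.25), 0.05)
})

test_that("a featureless frame is a detection error", {
  img <- matrix(7, 32, 32)
  frame <- microscopy_frame(img, reflection = img, pixel_size_um = 0.1)
  expect_error(locate_center(frame), class = "nanoheat_error_detection")
  expect_error(analyze_frame(frame), class = "nanoheat_error_detection")
})

test_that("fluorescence fallback for missing reflection warns", {
  img <- matrix(0, 32, 32); img[16, 16] <- 10
  frame <- microscopy_frame(img, pixel_size_um = 0.1)
  expect_warning(ctr <- locate_center(frame), "reflection")
  expect_equal(unname(ctr), c(16, 16))
})

test_that("radial profile of a uniform image is flat", {
  img <- matrix(3.5, 41, 41)
  frame <- microscopy_frame(img, pixel_size_um = 0.1)
  prof <- radial_profile(frame, c(21, 21))
  expect_true(all(prof$mean_intensity == 3.5))
  expect_true(!is.unsorted(prof$r_um, strictly = TRUE))
})

test_that("radial profile reproduces a sharp disk", {
  img <- matrix(1, 81, 81)
  r_px <- sqrt((col(img) - 41)^2 + (row(img) - 41)^2)
  img[r_px <= 20] <- 2
  frame <- microscopy_frame(img, pixel_size_um = 0.1)
  prof <- radial_profile(frame, c(41, 41))
  expect_true(all(prof$mean_intensity[prof$r_um < 2.0 - 0.1] == 2))
  expect_true(all(prof$mean_intensity[prof$r_um > 2.0 + 0.1] == 1))
})

test_that("the profile is invariant under exact 90-degree rotation", {
  sim <- make_footprint_frame(footprint_scene(D_m_um = 1.6, dim_px = 101L,
                                              center_px = c(51, 51),
                                              noise = "none"))
  img <- sim$frame$fluorescence
  rot <- t(img)[, rev(seq_len(ncol(img)))]     # 90-degree rotation
  f1 <- microscopy_frame(img, pixel_size_um = 0.08)
  f2 <- microscopy_frame(rot, pixel_size_um = 0.08)
  p1 <- radial_profile(f1, c(51, 51))
  p2 <- radial_profile(f2, c(51, 51))
  expect_equal(p1$mean_intensity, p2$mean_intensity, tolerance = 1e-6)
})

test_that("background over a constant ROI is that constant", {
  img <- matrix(100, 64, 64); img[30:34, 30:34] <- 500
  frame <- microscopy_frame(img, reflection = img, pixel_size_um = 0.1)
  expect_equal(measure_background(frame, c(2, 10, 2, 10)), 100)
})

test_that("background estimate obeys the CLT on noisy regions", {
  set.seed(71)
  img <- matrix(pmax(rnorm(100 * 100, 100, 5), 0), 100, 100)
  frame <- microscopy_frame(img, pixel_size_um = 0.1)
  bg <- measure_background(frame, c(1, 100, 1, 100))
  expect_lt(abs(bg - 100), 3 * 5 / sqrt(1e4))
})

test_that("a background ROI inside the melted zone is rejected", {
  img <- matrix(100, 64, 64)
  frame <- microscopy_frame(img, pixel_size_um = 0.1)
  expect_error(
    measure_background(frame, c(30, 36, 30, 36), center = c(32, 32),
                       expected_D_m_um = 1),
    class = "nanoheat_error_validation")
})

test_that("threshold crossing of a step profile is exact", {
  prof <- manual_profile(seq(0.05, 4, by = 0.1),
                         ifelse(seq(0.05, 4, by = 0.1) < 2, 200, 100))
  mr <- melting_radius(prof, background = 100)
  expect_equal(mr$Tr, 150)
  expect_equal(mr$D_m_um, 2.0)
  expect_false(mr$flag_diffraction)
})

test_that("a profile that never crosses the threshold is a field error", {
  prof <- manual_profile(seq(0.05, 4, by = 0.1),
                         200 - 5 * seq(0.05, 4, by = 0.1))
  expect_error(melting_radius(prof, background = 100),
               class = "nanoheat_error_field")
})

test_that("noiseless synthetic footprints are recovered within half a pixel", {
  for (truth in c(1.2, 2.05, 3.0)) {
    sim <- make_footprint_frame(footprint_scene(D_m_um = truth,
                                                psf_sigma_um = 0.09,
                                                noise = "none"))
    res <- analyze_frame(sim$frame, psf_sigma_um = 0.09)
    expect_lt(abs(res$D_m_um - truth), 0.5 * 0.08)
  }
})

test_that("D_m is exactly invariant under positive affine rescaling", {
  sim <- make_footprint_frame(footprint_scene(noise = "gaussian",
                                              noise_sd = 3, seed = 9))
  f0 <- sim$frame
  f1 <- microscopy_frame(3.7 * f0$fluorescence + 40,
                         reflection = 3.7 * f0$reflection + 40,
                         pixel_size_um = f0$pixel_size_um,
                         intensity_W_cm2 = f0$intensity_W_cm2)
  r0 <- analyze_frame(f0)
  r1 <- analyze_frame(f1)
  expect_equal(r1$D_m_um, r0$D_m_um, tolerance = 1e-12)
  expect_equal(r1$Tr, 3.7 * r0$Tr + 40, tolerance = 1e-12)
})

test_that("D_m moves less than half a pixel under image rotation", {
  sim <- make_footprint_frame(footprint_scene(D_m_um = 2.05,
                                              dim_px = 161L,
                                              center_px = c(81, 81),
                                              noise = "none"))
  f0 <- sim$frame
  rot <- rotate_image(f0$fluorescence, 37 * pi / 180, c(81, 81))
  f1 <- microscopy_frame(rot, reflection = f0$reflection,
                         pixel_size_um = f0$pixel_size_um)
  r0 <- analyze_frame(f0)
  r1 <- analyze_frame(f1)
  expect_lt(abs(r1$D_m_um - r0$D_m_um), 0.5 * f0$pixel_size_um)
})

test_that("sub-diffraction footprints are overestimated and flagged", {
  # the measured footprint cannot shrink below the PSF, so the bias is
  # positive in the diffraction-limited regime and fades as the true
  # footprint grows past the PSF width
  psf <- 0.15
  truths <- c(0.06, 0.10, 0.15, 0.22)
  bias <- vapply(truths, function(tr) {
    sim <- make_footprint_frame(footprint_scene(D_m_um = tr,
                                                psf_sigma_um = psf,
                                                pixel_size_um = 0.04,
                                                noise = "none"))
    res <- analyze_frame(sim$frame, psf_sigma_um = psf)
    expect_true(res$flag_diffraction)
    res$D_m_um - tr
  }, numeric(1))
  expect_true(all(bias > 0))
  expect_true(all(diff(bias) < 0))
  # well-resolved footprints carry no flag and next to no bias
  sim <- make_footprint_frame(footprint_scene(D_m_um = 2.4,
                                              psf_sigma_um = psf,
                                              noise = "none"))
  res <- analyze_frame(sim$frame, psf_sigma_um = psf)
  expect_false(res$flag_diffraction)
  expect_lt(abs(res$D_m_um - 2.4), 0.5 * 0.08)
})

test_that("footprints grow strictly with laser intensity", {
  series <- make_footprint_series(
    C_true = 5.4e-16, intensities_W_cm2 = c(1, 1.6, 2.4, 3.2) * 1e6,
    scene = footprint_scene(noise = "gaussian", noise_sd = 2, seed = 4))
  d <- purrr::map_dbl(series$frames, function(f) analyze_frame(f)$D_m_um)
  expect_true(all(diff(d) > 0))
})
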