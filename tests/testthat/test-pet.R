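const_volume <- function(value, dims = c(8L, 8L, 4L),
                         voxel = c(0.29, 0.29, 0.79)) {
  pet_volume(array(value, dims), voxel_dims_mm = voxel)
}

test_that("ROI statistics match hand arithmetic", {
  vol <- const_volume(5)
  roi <- array(TRUE, dim(vol$uptake))
  st <- uptake_stats(vol, roi)
  expect_equal(st$mean_IDg, 5)
  expect_equal(st$max_IDg, 5)
  expect_equal(st$sd_IDg, 0)

  vol2 <- const_volume(0)
  vol2$uptake[1:2] <- c(2, 4)
  roi2 <- array(FALSE, dim(vol2$uptake)); roi2[1:2] <- TRUE
  st2 <- uptake_stats(vol2, roi2)
  expect_equal(st2$mean_IDg, 3)
  expect_equal(st2$max_IDg, 4)
  expect_equal(st2$sd_IDg, sqrt(2))
})

test_that("empty or mismatched ROIs are rejected", {
  vol <- const_volume(5)
  expect_error(uptake_stats(vol, array(FALSE, dim(vol$uptake))),
               class = "nanoheat_error_validation")
  expect_error(uptake_stats(vol, array(TRUE, c(2L, 2L, 2L))),
               class = "nanoheat_error_validation")
})

test_that("phantom ROI means obey the CLT", {
  ph <- make_pet_phantom(pet_phantom_spec(seed = 21))
  st <- uptake_stats(ph$volume, ph$roi)
  expect_lt(abs(st$mean_IDg - 6), 3 * 1 / sqrt(st$n_voxels))
  expect_equal(st$sd_IDg, 1, tolerance = 0.05)
})

test_that("constant uptake yields zero low-uptake volume with a warning", {
  vol <- const_volume(5)
  roi <- array(TRUE, dim(vol$uptake))
  expect_warning(res <- low_uptake_volume(vol, roi), "degenerate")
  expect_equal(res$V_low_mm3, 0)
})

test_that("the Gaussian low-uptake fraction converges to Phi(-1.5)", {
  ph <- make_pet_phantom(pet_phantom_spec(seed = 8))
  res <- low_uptake_volume(ph$volume, ph$roi)
  n <- res$roi_volume_mm3 / prod(ph$volume$voxel_dims_mm)
  p <- pnorm(-1.5)
  expect_lt(abs(res$V_low_mm3 / res$roi_volume_mm3 - p),
            3 * sqrt(p * (1 - p) / n))
  expect_lte(res$V_low_mm3, res$roi_volume_mm3)
})

test_that("a cold lesion of 10% ROI volume is recovered within 10%", {
  spec <- pet_phantom_spec(lesion_radius_mm = 2.55,
                           lesion_center_mm = c(1.5, 0, 0),
                           lesion_uptake = 0.05, seed = 31)
  ph <- make_pet_phantom(spec)
  truth <- ph$truth$lesion_volume_mm3
  expect_gt(truth / ph$truth$roi_volume_mm3, 0.08)   # the intended regime
  res <- low_uptake_volume(ph$volume, ph$roi)
  expect_lt(abs(res$V_low_mm3 - truth) / truth, 0.10)
})

test_that("V_low is exactly invariant under positive affine transforms", {
  ph <- make_pet_phantom(pet_phantom_spec(core_radius_mm = 2,
                                          seed = 5))
  res0 <- low_uptake_volume(ph$volume, ph$roi)
  scaled <- pet_volume(2.3 * ph$volume$uptake + 1.7,
                       ph$volume$voxel_dims_mm, ph$volume$timepoint)
  res1 <- low_uptake_volume(scaled, ph$roi)
  expect_identical(res0$V_low_mm3, res1$V_low_mm3)
  expect_equal(res1$threshold_IDg, 2.3 * res0$threshold_IDg + 1.7,
               tolerance = 1e-12)
})

test_that("V_low grows monotonically as an established lesion grows", {
  # note: the threshold adapts to the scan's own mean and SD, so a *small*
  # lesion can depress V_low relative to the lesion-free phantom; the
  # monotone-growth property applies across lesioned phantoms
  v <- vapply(c(1.2, 2.0, 2.8), function(r) {
    spec <- pet_phantom_spec(lesion_radius_mm = r,
                             lesion_uptake = 0.05, seed = 17)
    ph <- make_pet_phantom(spec)
    low_uptake_volume(ph$volume, ph$roi)$V_low_mm3
  }, numeric(1))
  expect_true(all(diff(v) >= 0))
})

test_that("relative change behaves as a baseline-normalised ratio", {
  res <- tibble::tibble(V_low_mm3 = 60)
  expect_equal(relative_change(res, res), 1.0)
  expect_equal(relative_change(tibble::tibble(V_low_mm3 = 120), res), 2.0)
  expect_error(relative_change(res, tibble::tibble(V_low_mm3 = 0)),
               class = "nanoheat_error_baseline")
})

test_that("the scripted treatment pair triples the low-uptake volume", {
  pair <- make_treatment_pair(seed = 2)
  base <- low_uptake_volume(pair$baseline$volume, pair$baseline$roi)
  day0 <- low_uptake_volume(pair$day0$volume, pair$day0$roi)
  expect_equal(relative_change(day0, base), 3.0, tolerance = 0.10)
})

test_that("treatment effects are detected with high power", {
  detections <- vapply(1:25, function(seed) {
    base <- make_pet_phantom(pet_phantom_spec(
      core_radius_mm = 2.29, core_uptake = 0.5,
      core_center_mm = c(-2.65, 0, 0), seed = seed))
    # lesion just above 5% of the ROI
    day0 <- make_pet_phantom(pet_phantom_spec(
      core_radius_mm = 2.29, core_uptake = 0.5,
      core_center_mm = c(-2.65, 0, 0),
      lesion_radius_mm = 2.05, lesion_uptake = 0.05,
      lesion_center_mm = c(2.55, 0, 0), seed = seed + 1000L))
    rb <- low_uptake_volume(base$volume, base$roi)
    r0 <- low_uptake_volume(day0$volume, day0$roi)
    relative_change(r0, rb) > 1
  }, logical(1))
  expect_gte(mean(detections), 0.95)
})

test_that("cohort summaries are descriptive and order-invariant", {
  changes <- tibble::tibble(
    group = rep(c("AuNS", "saline"), each = 3),
    animal = paste0("m", 1:6),
    relative_change = c(2.8, 3.1, 3.3, 1.0, 1.1, 0.9))
  cs <- cohort_summary(changes)
  expect_equal(cs$mean[cs$group == "AuNS"], mean(c(2.8, 3.1, 3.3)))
  expect_false(any(cs$single_animal))
  shuffled <- changes[c(4, 2, 6, 1, 3, 5), ]
  expect_equal(cohort_summary(shuffled), cs)
  single <- cohort_summary(tibble::tibble(group = "g", animal = "m1",
                                          relative_change = 2))
  expect_true(single$single_animal)
  expect_equal(single$sd, 0)
})

test_that("%ID/g helper applies the dose and weight normalisation", {
  expect_equal(percent_id_per_g(1e4, 1e7, 20), 100 * 1e4 / 1e7 * 20)
})
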