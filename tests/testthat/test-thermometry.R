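test_that("the heating constant follows from the melting boundary", {
  env <- thermal_environment()
  fp <- tibble::tibble(D_m_um = 2.046, intensity_W_cm2 = 2.7e6)
  m <- fit_C(fp, env, R_nm = 75.65)
  # direct evaluation: C = (T_m - T_ambient) * D_m / I in SI units
  expect_equal(m$C_K_m3_W, (33.8 - 26.7) * 2.046e-6 / 2.7e10,
               tolerance = 1e-12)
  expect_equal(m$C_K_m3_W, 5.38e-16, tolerance = 1e-3)
})

test_that("C is inversely linear in intensity at fixed footprint", {
  fp <- tibble::tibble(D_m_um = c(2, 2), intensity_W_cm2 = c(1e6, 2e6))
  m <- fit_C(fp)
  expect_equal(m$C_K_m3_W[1L], 2 * m$C_K_m3_W[2L])
})

test_that("an inverted thermal environment is rejected", {
  env <- thermal_environment(T_m_C = 20, T_ambient_C = 26.7)
  fp <- tibble::tibble(D_m_um = 2, intensity_W_cm2 = 1e6)
  expect_error(fit_C(fp, env), "T_m must exceed")
})

test_that("the temperature profile obeys the 1/D law", {
  m <- fit_C(tibble::tibble(D_m_um = 2.046, intensity_W_cm2 = 2.7e6),
             R_nm = 75.65)
  dT_m <- temperature_at(m, 2.7e6, 2.046)
  expect_equal(dT_m, 33.8 - 26.7, tolerance = 1e-12)
  # surface temperature via the D_m/D_p rescaling identity
  dT_p <- surface_temperature(m, 2.7e6)$dT_surface_K
  expect_equal(dT_p, dT_m * 2.046 / (75.65e-3), tolerance = 1e-12)
  expect_equal(dT_p, 192, tolerance = 1e-3)
  # decay to zero far away
  expect_lt(temperature_at(m, 2.7e6, 500), 0.05)
  expect_error(temperature_at(m, 2.7e6, 0.05), "inside the particle")
})

test_that("surface temperatures scale linearly and flag saturation", {
  m <- fit_C(tibble::tibble(D_m_um = 2.046, intensity_W_cm2 = 2.7e6),
             R_nm = 75.65)
  st1 <- surface_temperature(m, 2.7e6)
  st10 <- surface_temperature(m, 2.7e7)
  expect_false(st1$saturated)
  expect_true(st10$saturated)
  expect_equal(st10$dT_surface_K, 10 * st1$dT_surface_K)
  expect_error(surface_temperature(m, 0), "positive")
})

test_that("the conduction balance reproduces the measured cross-section", {
  env <- thermal_environment()
  expect_equal(env$k, 0.855)
  c_abs <- absorption_cross_section(192, 2.7e6, 75.65, env)
  expect_equal(c_abs, 5781, tolerance = 2e-3)
  expect_equal(absorption_cross_section(0, 1e6, 75, env), 0)
})

test_that("both heating relations agree algebraically: C_abs = 4 pi k C", {
  env <- thermal_environment()
  set.seed(13)
  for (i in 1:25) {
    C <- 10^runif(1, -17, -14)
    R_nm <- runif(1, 20, 200)
    I <- 10^runif(1, 5, 7)
    m <- tibble::tibble(C_K_m3_W = C, R_nm = R_nm)
    dT_p <- C * (I * 1e4) / (R_nm * 1e-9)
    via_eq2 <- absorption_cross_section(dT_p, I, R_nm, env)
    via_identity <- 4 * pi * env$k * C * 1e18
    expect_equal(via_eq2, via_identity, tolerance = 1e-12)
    expect_equal(cross_section_from_model(m, env), via_identity,
                 tolerance = 1e-12)
  }
})

test_that("noiseless proportional data return the exact slope", {
  s <- tibble::tibble(power = c(0.5, 1, 2, 4) * 1e-3,
                      dT_K = 573.7 * c(0.5, 1, 2, 4) * 1e-3)
  g <- suppressWarnings(glance(fit_heating_slope(s)))
  expect_equal(g$slope_K_W, 573.7, tolerance = 1e-12)
  expect_equal(g$n_saturated, 0L)
})

test_that("saturated points are excluded without changing the slope", {
  s <- tibble::tibble(power = c(1, 2, 3) * 1e-3,
                      dT_K = 573.7 * c(1, 2, 3) * 1e-3)
  g0 <- suppressWarnings(glance(fit_heating_slope(s)))
  s_plus <- dplyr::bind_rows(s, tibble::tibble(power = 0.5, dT_K = 230))
  g1 <- suppressWarnings(glance(fit_heating_slope(s_plus)))
  expect_equal(g1$slope_K_W, g0$slope_K_W)
  expect_equal(g1$n_saturated, 1L)
  all_sat <- tibble::tibble(power = c(1, 2), dT_K = c(250, 260))
  expect_error(fit_heating_slope(all_sat), "saturation")
})

test_that("slope recovery is calibrated against its standard errors", {
  true_slope <- 573.7
  powers <- seq(1, 12) * 1e-3
  hits <- vapply(1:400, function(seed) {
    sim <- make_heating_series(C_true = 5e-16, R_nm = 75,
                               intensities_W_cm2 = powers,
                               noise_sd_K = 4, seed = seed)
    # rescale the clean proportional series to the target slope
    s <- tibble::tibble(power = powers,
                        dT_K = true_slope * powers +
                          (sim$series$dT_K - 5e-16 * powers * 1e4 / 75e-9))
    g <- suppressWarnings(glance(fit_heating_slope(s)))
    abs(g$slope_K_W - true_slope) <= 3 * g$std_error
  }, logical(1))
  expect_gte(mean(hits), 0.98)
})

test_that("a footprint series round-trips the heating constant", {
  C_true <- 5.38e-16
  series <- make_footprint_series(
    C_true = C_true, intensities_W_cm2 = c(1.5, 2.2, 3.0) * 1e6,
    scene = footprint_scene(noise = "none"))
  fits <- purrr::map_dbl(series$frames, function(f) {
    fit_C(analyze_frame(f), R_nm = 75)$C_K_m3_W
  })
  expect_true(all(abs(fits - C_true) / C_true < 0.01))
})

test_that("tidy and glance expose the fit in broom shape", {
  s <- tibble::tibble(power = 1:5 * 1e-3, dT_K = 500 * 1:5 * 1e-3 + 0.1)
  fit <- fit_heating_slope(s)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std_error", "conf_low",
                     "conf_high"))
  g <- glance(fit)
  expect_true(g$conf_low < g$slope_K_W & g$slope_K_W < g$conf_high)
  p <- ggplot2::ggplot_build(autoplot(fit))
  expect_s3_class(p$plot, "ggplot")
})
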