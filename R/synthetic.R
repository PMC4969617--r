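#' Run code with a local, restored RNG state
#'
#' All generators take an explicit seed and leave the caller's RNG
#' untouched.
#' @noRd
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic footprint scene description
#'
#' Ground truth for one simulated irradiated-particle frame: a hard
#' disk of fluid-phase (bright) bilayer of radius `D_m_um` on a
#' gel-phase (dim) background, blurred by a Gaussian PSF, with optional
#' noise. The fluid phase must be brighter than the gel phase: the
#' phase-sensitive fluorophore partitions into the melted region.
#'
#' @param D_m_um True footprint radius, micrometres.
#' @param gel_intensity,fluid_intensity Phase intensity levels;
#'   `fluid_intensity > gel_intensity`.
#' @param psf_sigma_um Gaussian PSF sigma, micrometres (>= 0; 0 renders
#'   an unblurred two-level disk). Default 0.073 um = 0.21 lambda / NA
#'   for 488 nm light and a 1.4 NA objective.
#' @param pixel_size_um Pixel size, micrometres.
#' @param dim_px Image side length in pixels (square frames).
#' @param center_px Particle center `c(x, y)` in pixel coordinates;
#'   default the field center.
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param poisson_gain Intensity units per detected photon.
#' @param intensity_W_cm2 Laser intensity metadata attached to the
#'   frame.
#' @param T_ambient_C Ambient temperature metadata.
#' @param seed Integer seed; same seed, same frame, bit for bit.
#' @return A `footprint_scene` list.
#' @export
footprint_scene <- function(D_m_um = 2.05,
                            gel_intensity = 100,
                            fluid_intensity = 200,
                            psf_sigma_um = 0.073,
                            pixel_size_um = 0.08,
                            dim_px = 160L,
                            center_px = NULL,
                            noise = c("none", "gaussian", "poisson"),
                            noise_sd = 5,
                            poisson_gain = 1,
                            intensity_W_cm2 = 2.7e6,
                            T_ambient_C = 26.7,
                            seed = 1L) {
  noise <- match.arg(noise)
  if (fluid_intensity <= gel_intensity) {
    abort("fluid_intensity must exceed gel_intensity",
          class = "nanoheat_error_validation")
  }
  stopifnot(D_m_um > 0, psf_sigma_um >= 0, pixel_size_um > 0,
            dim_px >= 8L)
  center_px <- center_px %||% rep((dim_px + 1) / 2, 2L)
  field_half_um <- (dim_px / 2) * pixel_size_um
  if (D_m_um >= 0.7 * field_half_um) {
    abort("true D_m does not fit the field with margin for background",
          class = "nanoheat_error_validation")
  }
  structure(
    list(D_m_um = D_m_um, gel_intensity = gel_intensity,
         fluid_intensity = fluid_intensity, psf_sigma_um = psf_sigma_um,
         pixel_size_um = pixel_size_um, dim_px = as.integer(dim_px),
         center_px = center_px, noise = noise, noise_sd = noise_sd,
         poisson_gain = poisson_gain,
         intensity_W_cm2 = intensity_W_cm2, T_ambient_C = T_ambient_C,
         seed = as.integer(seed)),
    class = "footprint_scene")
}

# Gaussian blur by multiplication with the analytic transfer function in
# Fourier space (periodic; the scene is constant near the boundary so
# wrap-around is immaterial).
gaussian_blur_fft <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  d <- dim(img)
  fy <- c(0:(d[1L] %/% 2), -((d[1L] - d[1L] %/% 2 - 1):1)) / d[1L]
  fx <- c(0:(d[2L] %/% 2), -((d[2L] - d[2L] %/% 2 - 1):1)) / d[2L]
  h <- exp(-2 * pi^2 * sigma_px^2 * outer(fy^2, fx^2, `+`))
  Re(fft(fft(img) * h, inverse = TRUE)) / length(img)
}

#' Generate a synthetic footprint frame
#'
#' Renders the scene's disk on a supersampled grid (factor 4), applies
#' the Gaussian PSF, box-averages down to the pixel grid, and adds
#' noise. The reflection channel is a PSF-blurred point emitter at the
#' particle center. Deterministic per seed.
#'
#' @param scene A [footprint_scene()].
#' @return List with `frame` (a [microscopy_frame()]) and `truth` (a
#'   one-row tibble of the generating parameters).
#' @export
make_footprint_frame <- function(scene) {
  stopifnot(inherits(scene, "footprint_scene"))
  n <- scene$dim_px
  px <- scene$pixel_size_um
  s <- if (scene$psf_sigma_um > 0) 4L else 1L

  # coarse pixel i covers [i - 0.5, i + 0.5]; subpixel j of it sits at
  # i - 0.5 + (j - 0.5)/s
  sub <- rep(seq_len(n), each = s) - 0.5 + (rep(seq_len(s), n) - 0.5) / s
  dx2 <- outer((sub - scene$center_px[2L])^2,
               (sub - scene$center_px[1L])^2, `+`)   # rows = y, cols = x
  r_um <- sqrt(dx2) * px
  img <- matrix(scene$gel_intensity, n * s, n * s)
  img[r_um <= scene$D_m_um] <- scene$fluid_intensity
  img <- gaussian_blur_fft(img, scene$psf_sigma_um / px * s)
  if (s > 1L) {  # box average each s x s block
    img <- apply(array(img, c(s, n, s * n)), c(2, 3), mean)
    img <- t(apply(array(t(img), c(s, n, n)), c(2, 3), mean))
  }

  xs <- seq_len(n)
  g1x <- exp(-((xs - scene$center_px[1L])^2) * px^2 /
               (2 * max(scene$psf_sigma_um, 0.5 * px)^2))
  g1y <- exp(-((xs - scene$center_px[2L])^2) * px^2 /
               (2 * max(scene$psf_sigma_um, 0.5 * px)^2))
  refl <- 10 + 1000 * outer(g1y, g1x)

  out <- with_local_seed(scene$seed, {
    fl <- switch(scene$noise,
      none = img,
      gaussian = img + rnorm(length(img), 0, scene$noise_sd),
      poisson = matrix(
        rpois(length(img), img / scene$poisson_gain) * scene$poisson_gain,
        nrow(img)))
    rf <- switch(scene$noise,
      none = refl,
      gaussian = refl + rnorm(length(refl), 0, scene$noise_sd),
      poisson = matrix(
        rpois(length(refl), refl / scene$poisson_gain) *
          scene$poisson_gain, nrow(refl)))
    list(fl = pmax(fl, 0), rf = pmax(rf, 0))
  })

  frame <- microscopy_frame(out$fl, reflection = out$rf,
                            pixel_size_um = px,
                            intensity_W_cm2 = scene$intensity_W_cm2,
                            T_ambient_C = scene$T_ambient_C)
  truth <- tibble::tibble(
    center_x = scene$center_px[1L], center_y = scene$center_px[2L],
    D_m_um = scene$D_m_um, psf_sigma_um = scene$psf_sigma_um,
    pixel_size_um = px, noise = scene$noise, seed = scene$seed,
    intensity_W_cm2 = scene$intensity_W_cm2)
  list(frame = frame, truth = truth)
}

#' Generate a laser-intensity series of footprint frames
#'
#' Inverts the point-source heating relation at the melting boundary:
#' the true footprint radius at intensity I is
#' `D_m = C_true * I / (T_m - T_ambient)`. One frame per intensity;
#' frame seeds are derived from `scene$seed`.
#'
#' @param C_true True heating constant, K m^3/W.
#' @param env A [thermal_environment()].
#' @param intensities_W_cm2 Increasing positive laser intensities.
#' @param scene Scene defaults (its `D_m_um` is overridden per frame).
#' @return List with `frames` (list of [microscopy_frame()]) and
#'   `truth` (tibble, one row per frame).
#' @export
make_footprint_series <- function(C_true, env = thermal_environment(),
                                  intensities_W_cm2,
                                  scene = footprint_scene()) {
  stopifnot(C_true > 0, all(intensities_W_cm2 > 0),
            inherits(env, "thermal_environment"))
  dT_m <- env$T_m_C - env$T_ambient_C
  stopifnot(dT_m > 0)
  D_m_um <- C_true * (intensities_W_cm2 * 1e4) / dT_m * 1e6
  sims <- purrr::imap(intensities_W_cm2, function(I, i) {
    sc <- scene
    sc$D_m_um <- D_m_um[i]
    sc$intensity_W_cm2 <- I
    sc$T_ambient_C <- env$T_ambient_C
    sc$seed <- scene$seed + i
    make_footprint_frame(sc)
  })
  list(frames = purrr::map(sims, "frame"),
       truth = dplyr::bind_rows(purrr::map(sims, "truth")))
}

#' Synthetic PET phantom specification
#'
#' Describes a tumor phantom: an ellipsoidal tumor with truncated-normal
#' bulk uptake, an optional necrotic core and an optional cold
#' (treatment) lesion, both spherical, on the scanner's voxel grid.
#'
#' @param grid_dim Integer length-3 grid shape; default `c(48, 48, 24)`.
#' @param voxel_dims_mm Voxel size; default `c(0.29, 0.29, 0.79)` mm.
#' @param tumor_semiaxes_mm Ellipsoid semi-axes; the default gives a
#'   tumor of about 700 mm^3.
#' @param bulk_mean,bulk_sd Bulk uptake Normal parameters (%ID/g),
#'   truncated at zero (negligible for `bulk_mean/bulk_sd >= 4`).
#' @param core_radius_mm,core_uptake Necrotic core sphere (radius 0
#'   disables) and its uptake.
#' @param core_center_mm Core center offset from the tumor center, mm.
#' @param lesion_radius_mm,lesion_uptake Cold treatment lesion (radius 0
#'   disables) and its uptake.
#' @param lesion_center_mm Lesion center offset, mm.
#' @param background_uptake Uptake outside the tumor.
#' @param timepoint Label for the generated volume.
#' @param seed Integer seed.
#' @return A `pet_phantom_spec` list.
#' @export
pet_phantom_spec <- function(grid_dim = c(48L, 48L, 24L),
                             voxel_dims_mm = c(0.29, 0.29, 0.79),
                             tumor_semiaxes_mm = c(5.5, 5.5, 5.6),
                             bulk_mean = 6, bulk_sd = 1,
                             core_radius_mm = 0, core_uptake = 0.5,
                             core_center_mm = c(0, 0, 0),
                             lesion_radius_mm = 0, lesion_uptake = 0.05,
                             lesion_center_mm = c(0, 0, 0),
                             background_uptake = 0.5,
                             timepoint = "baseline",
                             seed = 1L) {
  stopifnot(length(grid_dim) == 3L, all(grid_dim >= 4L),
            length(voxel_dims_mm) == 3L, all(voxel_dims_mm > 0),
            length(tumor_semiaxes_mm) == 3L, all(tumor_semiaxes_mm > 0),
            bulk_sd >= 0, core_radius_mm >= 0, lesion_radius_mm >= 0)
  spec <- structure(
    list(grid_dim = as.integer(grid_dim), voxel_dims_mm = voxel_dims_mm,
         tumor_semiaxes_mm = tumor_semiaxes_mm,
         bulk_mean = bulk_mean, bulk_sd = bulk_sd,
         core_radius_mm = core_radius_mm, core_uptake = core_uptake,
         core_center_mm = core_center_mm,
         lesion_radius_mm = lesion_radius_mm,
         lesion_uptake = lesion_uptake,
         lesion_center_mm = lesion_center_mm,
         background_uptake = background_uptake,
         timepoint = timepoint, seed = as.integer(seed)),
    class = "pet_phantom_spec")
  for (part in c("core", "lesion")) {
    r <- spec[[paste0(part, "_radius_mm")]]
    ctr <- spec[[paste0(part, "_center_mm")]]
    if (r > 0 && sqrt(sum(ctr^2 / tumor_semiaxes_mm^2)) > 1) {
      abort(paste0(part, " center lies outside the tumor ellipsoid"),
            class = "nanoheat_error_validation")
    }
  }
  spec
}

#' Generate a PET phantom
#'
#' Voxelises the tumor ellipsoid (the ROI), draws bulk uptake from
#' `Normal(bulk_mean, bulk_sd)` truncated at zero, then paints the
#' necrotic core and the cold lesion at their fixed uptakes.
#' Deterministic per seed.
#'
#' @param spec A [pet_phantom_spec()].
#' @return List with `volume` (a [pet_volume()]), `roi` (logical
#'   array), and `truth` (one-row tibble including the voxelised core
#'   and lesion volumes in mm^3).
#' @export
make_pet_phantom <- function(spec) {
  stopifnot(inherits(spec, "pet_phantom_spec"))
  d <- spec$grid_dim
  vx <- spec$voxel_dims_mm
  coords <- purrr::map2(d, vx, function(n, v) ((seq_len(n) - 0.5) - n / 2) * v)
  cx <- array(rep(coords[[1L]], times = d[2L] * d[3L]), d)
  cy <- array(rep(rep(coords[[2L]], each = d[1L]), times = d[3L]), d)
  cz <- array(rep(coords[[3L]], each = d[1L] * d[2L]), d)
  roi <- (cx / spec$tumor_semiaxes_mm[1L])^2 +
    (cy / spec$tumor_semiaxes_mm[2L])^2 +
    (cz / spec$tumor_semiaxes_mm[3L])^2 <= 1
  sphere_mask <- function(center, radius) {
    if (radius <= 0) return(array(FALSE, d))
    (cx - center[1L])^2 + (cy - center[2L])^2 + (cz - center[3L])^2 <=
      radius^2
  }
  core <- sphere_mask(spec$core_center_mm, spec$core_radius_mm)
  lesion <- sphere_mask(spec$lesion_center_mm, spec$lesion_radius_mm)
  for (part in c("core", "lesion")) {
    mask <- if (part == "core") core else lesion
    if (any(mask & !roi)) {
      abort(paste0(part, " sphere is not contained in the tumor ",
                   "ellipsoid"), class = "nanoheat_error_validation")
    }
  }
  uptake <- with_local_seed(spec$seed, {
    u <- array(spec$background_uptake, d)
    u[roi] <- pmax(rnorm(sum(roi), spec$bulk_mean, spec$bulk_sd), 0)
    u
  })
  uptake[core] <- spec$core_uptake
  uptake[lesion] <- spec$lesion_uptake
  voxel_mm3 <- prod(vx)
  truth <- tibble::tibble(
    timepoint = spec$timepoint,
    roi_volume_mm3 = sum(roi) * voxel_mm3,
    core_volume_mm3 = sum(core) * voxel_mm3,
    lesion_volume_mm3 = sum(lesion) * voxel_mm3,
    cold_volume_mm3 = sum(core | lesion) * voxel_mm3,
    bulk_mean = spec$bulk_mean, bulk_sd = spec$bulk_sd,
    seed = spec$seed)
  list(volume = pet_volume(uptake, vx, timepoint = spec$timepoint),
       roi = roi, truth = truth)
}

#' Scripted baseline / day-0 phantom pair
#'
#' A treated animal emulated as two phantoms on a common grid: at
#' baseline a necrotic core of about 50 mm^3; at day 0 the same core
#' plus a cold ablation lesion of about 100 mm^3, so the low-uptake
#' volume triples.
#'
#' @param seed Integer seed (baseline uses `seed`, day 0 `seed + 1`).
#' @return List with `baseline`, `day0` (each a [make_pet_phantom()]
#'   result).
#' @export
make_treatment_pair <- function(seed = 1L) {
  core_r <- (3 * 50 / (4 * pi))^(1 / 3)      # sphere of 50 mm^3
  lesion_r <- (3 * 100 / (4 * pi))^(1 / 3)   # sphere of 100 mm^3
  base_spec <- pet_phantom_spec(
    core_radius_mm = core_r, core_uptake = 0.5,
    core_center_mm = c(-2.65, 0, 0),
    timepoint = "baseline", seed = seed)
  day0_spec <- base_spec
  day0_spec$lesion_radius_mm <- lesion_r
  day0_spec$lesion_center_mm <- c(2.55, 0, 0)
  day0_spec$timepoint <- "day0"
  day0_spec$seed <- as.integer(seed + 1L)
  list(baseline = make_pet_phantom(base_spec),
       day0 = make_pet_phantom(day0_spec))
}

#' Synthetic heating-series generator
#'
#' Surface temperature increases `dT = C_true * I / R + noise`, capped
#' at the saturation temperature; seeded and deterministic.
#'
#' @param C_true True heating constant, K m^3/W.
#' @param R_nm Particle radius, nm.
#' @param intensities_W_cm2 Strictly increasing positive intensities.
#' @param noise_sd_K Gaussian noise SD on dT, K.
#' @param saturation_cap_C Absolute cap, degrees C.
#' @param T_ambient_C Ambient temperature, degrees C.
#' @param seed Integer seed.
#' @return List with `series` (tibble `power`, `dT_K`,
#'   `saturated_truth`) and `truth` (one-row tibble).
#' @export
make_heating_series <- function(C_true, R_nm, intensities_W_cm2,
                                noise_sd_K = 0, saturation_cap_C = 240,
                                T_ambient_C = 26.7, seed = 1L) {
  stopifnot(C_true > 0, R_nm > 0, all(intensities_W_cm2 > 0),
            !is.unsorted(intensities_W_cm2, strictly = TRUE),
            noise_sd_K >= 0)
  dT_clean <- C_true * (intensities_W_cm2 * 1e4) / (R_nm * 1e-9)
  dT <- with_local_seed(seed, {
    dT_clean + if (noise_sd_K > 0) {
      rnorm(length(dT_clean), 0, noise_sd_K)
    } else 0
  })
  cap_K <- saturation_cap_C - T_ambient_C
  saturated <- dT > cap_K
  dT[saturated] <- cap_K
  list(series = tibble::tibble(power = intensities_W_cm2, dT_K = dT,
                               saturated_truth = saturated),
       truth = tibble::tibble(C_true = C_true, R_nm = R_nm,
                              noise_sd_K = noise_sd_K,
                              saturation_cap_C = saturation_cap_C,
                              T_ambient_C = T_ambient_C, seed = seed))
}
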