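#' Single-particle microscopy frame
#'
#' Bundles the fluorescence image (and optional reflection image) of one
#' irradiated particle with its acquisition metadata. Pixel centers sit
#' at integer coordinates with the origin at the top-left pixel center:
#' `x` runs along matrix columns, `y` along rows, both starting at 1.
#'
#' @param fluorescence Numeric matrix of fluorescence intensities.
#' @param reflection Optional numeric matrix (same shape) of the
#'   reflection channel used for particle localisation.
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @param intensity_W_cm2 Laser intensity at the particle, W/cm2.
#' @param T_ambient_C Ambient temperature, degrees C.
#' @return A `microscopy_frame` list.
#' @export
microscopy_frame <- function(fluorescence, reflection = NULL,
                             pixel_size_um, intensity_W_cm2 = NA_real_,
                             T_ambient_C = 26.7) {
  stopifnot(is.matrix(fluorescence), is.numeric(fluorescence))
  if (any(!is.finite(fluorescence)) || any(fluorescence < 0)) {
    abort("fluorescence intensities must be finite and non-negative",
          class = "nanoheat_error_validation")
  }
  if (!is.null(reflection)) {
    stopifnot(is.matrix(reflection))
    if (!identical(dim(reflection), dim(fluorescence))) {
      abort("reflection and fluorescence grids must have the same shape",
            class = "nanoheat_error_validation")
    }
  }
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("pixel_size_um must be positive", class = "nanoheat_error_validation")
  }
  structure(
    list(fluorescence = fluorescence, reflection = reflection,
         pixel_size_um = pixel_size_um,
         intensity_W_cm2 = intensity_W_cm2,
         T_ambient_C = T_ambient_C),
    class = "microscopy_frame")
}

#' @export
print.microscopy_frame <- function(x, ...) {
  d <- dim(x$fluorescence)
  cat(sprintf("<microscopy_frame> %d x %d px (%.3g um/px)%s\n",
              d[1L], d[2L], x$pixel_size_um,
              if (is.null(x$reflection)) "" else " + reflection"))
  if (is.finite(x$intensity_W_cm2)) {
    cat(sprintf("  I = %.4g W/cm2, T_ambient = %.1f C\n",
                x$intensity_W_cm2, x$T_ambient_C))
  }
  invisible(x)
}

#' Locate the particle center
#'
#' Intensity-weighted centroid after background subtraction (the median
#' intensity is taken as the background level, negative residuals are
#' clipped). The reflection channel is preferred when present; falling
#' back to fluorescence is flagged with a warning since the fluorescence
#' footprint is broader than the particle.
#'
#' @param frame A [microscopy_frame()].
#' @return Named numeric vector `c(x, y)` in (sub-)pixel coordinates.
#' @export
locate_center <- function(frame) {
  stopifnot(inherits(frame, "microscopy_frame"))
  img <- frame$reflection
  if (is.null(img)) {
    warn("no reflection channel; locating center on fluorescence")
    img <- frame$fluorescence
  }
  bg <- median(img)
  w <- pmax(img - bg, 0)
  if (sum(w) <= 0) {
    abort("no pixel rises above background; particle not detectable",
          class = "nanoheat_error_detection")
  }
  xs <- col(img)
  ys <- row(img)
  c(x = sum(w * xs) / sum(w), y = sum(w * ys) / sum(w))
}

#' Rotationally averaged radial intensity profile
#'
#' Averages the fluorescence intensity over annuli around `center`
#' (the 0 to 2 pi average at every distance). Annuli are clipped at the
#' image boundary; only bins containing at least one pixel are
#' reported.
#'
#' @param frame A [microscopy_frame()].
#' @param center `c(x, y)` in pixel coordinates, inside the image.
#' @param bin_width_um Radial bin width in micrometres; defaults to one
#'   pixel.
#' @return A `radial_profile` tibble: `r_um` (bin centers),
#'   `mean_intensity`, `n_px`.
#' @export
radial_profile <- function(frame, center, bin_width_um = NULL) {
  stopifnot(inherits(frame, "microscopy_frame"), length(center) == 2L)
  img <- frame$fluorescence
  d <- dim(img)
  if (center[1L] < 1 || center[1L] > d[2L] ||
      center[2L] < 1 || center[2L] > d[1L]) {
    abort("center must lie inside the image",
          class = "nanoheat_error_validation")
  }
  px <- frame$pixel_size_um
  bin_width_um <- bin_width_um %||% px
  stopifnot(bin_width_um > 0)
  r <- sqrt((col(img) - center[1L])^2 + (row(img) - center[2L])^2) * px
  bin <- floor(r / bin_width_um)
  mean_i <- tapply(as.vector(img), as.vector(bin), mean)
  n_px <- tapply(as.vector(img), as.vector(bin), length)
  idx <- as.integer(names(mean_i))
  out <- tibble::tibble(
    r_um = (idx + 0.5) * bin_width_um,
    mean_intensity = as.numeric(mean_i),
    n_px = as.integer(n_px))
  out <- out[order(out$r_um), ]
  structure(out, bin_width_um = bin_width_um,
            class = c("radial_profile", class(out)))
}

#' Mean background intensity in a rectangular ROI
#'
#' The background region must be several micrometres away from the
#' melted zone: when `center` and `expected_D_m_um` are supplied, any
#' overlap between the rectangle and a disk of radius
#' `2 * expected_D_m_um` around the center is a validation error.
#'
#' @param frame A [microscopy_frame()].
#' @param roi_bg Rectangle `c(x0, x1, y0, y1)` in pixel coordinates
#'   (inclusive).
#' @param center Optional particle center `c(x, y)` for the overlap
#'   check.
#' @param expected_D_m_um Optional expected footprint radius for the
#'   overlap check.
#' @return Mean intensity over the ROI.
#' @export
measure_background <- function(frame, roi_bg, center = NULL,
                               expected_D_m_um = NULL) {
  stopifnot(inherits(frame, "microscopy_frame"), length(roi_bg) == 4L)
  d <- dim(frame$fluorescence)
  xr <- sort(round(roi_bg[1:2])); yr <- sort(round(roi_bg[3:4]))
  xr <- pmax(pmin(xr, d[2L]), 1L); yr <- pmax(pmin(yr, d[1L]), 1L)
  if (!is.null(center) && !is.null(expected_D_m_um)) {
    # nearest point of the rectangle to the center, in um
    nx <- pmin(pmax(center[1L], xr[1L]), xr[2L])
    ny <- pmin(pmax(center[2L], yr[1L]), yr[2L])
    dist_um <- sqrt((nx - center[1L])^2 + (ny - center[2L])^2) *
      frame$pixel_size_um
    if (dist_um < 2 * expected_D_m_um) {
      abort("background ROI overlaps the melted zone (within 2 x D_m)",
            class = "nanoheat_error_validation")
    }
  }
  mean(frame$fluorescence[yr[1L]:yr[2L], xr[1L]:xr[2L]])
}

# Default background: annulus between 75% and 95% of the field
# half-width, i.e. several micrometres outside any footprint that fits
# in the field but still fully inside the image.
background_annulus <- function(frame, center) {
  img <- frame$fluorescence
  px <- frame$pixel_size_um
  half_width_um <- min(dim(img)) / 2 * px
  r <- sqrt((col(img) - center[1L])^2 + (row(img) - center[2L])^2) * px
  sel <- r >= 0.75 * half_width_um & r <= 0.95 * half_width_um
  if (!any(sel)) {
    abort("default background annulus contains no pixels",
          class = "nanoheat_error_validation")
  }
  mean(img[sel])
}

#' Melted-footprint radius from a radial profile
#'
#' The melted-region maximum is the largest profile value within
#' `roi_melted_um` of the center; the threshold is the intensity halfway
#' between that maximum and the background,
#' `Tr = background + 0.5 (melted_max - background)`. `D_m` is the first
#' outward crossing of the profile below `Tr` past the maximum, linearly
#' interpolated between bin centers. Footprints smaller than twice the
#' imaging PSF width are flagged diffraction-limited (their `D_m`, and
#' hence inferred surface temperatures, are slightly overestimated).
#'
#' @param profile A [radial_profile()].
#' @param background Background intensity, e.g. from
#'   [measure_background()].
#' @param roi_melted_um Radius of the melted-region ROI used for the
#'   maximum; default 2.
#' @param psf_sigma_um Gaussian PSF sigma of the imaging system in
#'   micrometres; default 0.073 (488 nm light, NA 1.4).
#' @return One-row tibble: `D_m_um`, `Tr`, `melted_max`, `background`,
#'   `flag_diffraction`.
#' @export
melting_radius <- function(profile, background, roi_melted_um = 2,
                           psf_sigma_um = 0.073) {
  stopifnot(inherits(profile, "radial_profile"), nrow(profile) >= 2L)
  inner <- profile[profile$r_um <= roi_melted_um, ]
  if (nrow(inner) == 0L) inner <- profile[1L, ]
  melted_max <- max(inner$mean_intensity)
  if (melted_max <= background) {
    abort("profile maximum does not exceed background; no melted zone",
          class = "nanoheat_error_detection")
  }
  tr <- background + 0.5 * (melted_max - background)
  i_max <- which(profile$mean_intensity == melted_max &
                   profile$r_um <= max(inner$r_um))[1L]
  y <- profile$mean_intensity
  r <- profile$r_um
  below <- which(y < tr & seq_along(y) > i_max)
  if (length(below) == 0L) {
    abort("profile never drops below the threshold: footprint exceeds field",
          class = "nanoheat_error_field")
  }
  j <- below[1L]
  # linear interpolation between the last bin at/above Tr and bin j
  r0 <- r[j - 1L]; y0 <- y[j - 1L]
  r1 <- r[j]; y1 <- y[j]
  D_m <- r0 + (y0 - tr) / (y0 - y1) * (r1 - r0)
  tibble::tibble(D_m_um = D_m, Tr = tr, melted_max = melted_max,
                 background = background,
                 flag_diffraction = D_m < 2 * psf_sigma_um)
}

#' Analyze one frame into a footprint measurement
#'
#' Pipeline composition: [locate_center()], [radial_profile()],
#' background estimation (a user rectangle via `roi_bg`, else the
#' default annulus), [melting_radius()]. Errors are re-thrown tagged
#' with the stage that produced them.
#'
#' @param frame A [microscopy_frame()].
#' @param roi_bg Optional background rectangle `c(x0, x1, y0, y1)` in
#'   pixels; default is an annulus at 75--95% of the field half-width.
#' @param bin_width_um Radial bin width; default one pixel.
#' @param roi_melted_um Melted-region ROI radius in micrometres.
#' @param psf_sigma_um Imaging PSF sigma in micrometres.
#' @return One-row tibble: `center_x`, `center_y`, `D_m_um`, `Tr`,
#'   `background`, `melted_max`, `flag_diffraction`,
#'   `intensity_W_cm2`.
#' @export
#' @examples
#' sc <- footprint_scene(D_m_um = 1.5, noise = "none")
#' frame <- make_footprint_frame(sc)$frame
#' analyze_frame(frame)
analyze_frame <- function(frame, roi_bg = NULL, bin_width_um = NULL,
                          roi_melted_um = 2, psf_sigma_um = 0.073) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)),
            class = class(e)[1L])
    })
  }
  center <- stage("locate_center", locate_center(frame))
  profile <- stage("radial_profile",
                   radial_profile(frame, center, bin_width_um))
  background <- stage("measure_background", {
    if (is.null(roi_bg)) background_annulus(frame, center)
    else measure_background(frame, roi_bg, center = center)
  })
  mr <- stage("melting_radius",
              melting_radius(profile, background,
                             roi_melted_um = roi_melted_um,
                             psf_sigma_um = psf_sigma_um))
  tibble::tibble(center_x = center[["x"]], center_y = center[["y"]],
                 D_m_um = mr$D_m_um, Tr = mr$Tr,
                 background = mr$background, melted_max = mr$melted_max,
                 flag_diffraction = mr$flag_diffraction,
                 intensity_W_cm2 = frame$intensity_W_cm2)
}

#' Plot a radial profile
#'
#' @param object A [radial_profile()].
#' @param measurement Optional [melting_radius()]/[analyze_frame()] row;
#'   draws the threshold and `D_m`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radial_profile <- function(object, measurement = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$r_um, .data$mean_intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression("distance from particle (" * mu * "m)"),
                  y = "mean intensity") +
    ggplot2::theme_minimal()
  if (!is.null(measurement)) {
    p <- p +
      ggplot2::geom_hline(yintercept = measurement$Tr, linetype = 3) +
      ggplot2::geom_vline(xintercept = measurement$D_m_um, linetype = 2)
  }
  p
}
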