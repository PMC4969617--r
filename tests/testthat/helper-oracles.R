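# Independent oracles used across the suite. These deliberately avoid the
# package's recurrence-based code paths: Riccati-Bessel functions are
# written out in closed form (valid for real or complex argument), so
# Mie coefficients can be checked against a direct series evaluation.

psi_closed <- function(n, z) {
  switch(as.character(n),
    "0" = sin(z),
    "1" = sin(z) / z - cos(z),
    "2" = (3 / z^2 - 1) * sin(z) - (3 / z) * cos(z),
    "3" = (15 / z^3 - 6 / z) * sin(z) - (15 / z^2 - 1) * cos(z),
    "4" = (105 / z^4 - 45 / z^2 + 1) * sin(z) -
      (105 / z^3 - 10 / z) * cos(z),
    stop("psi_closed only implemented for n <= 4"))
}

chi_closed <- function(n, z) {
  switch(as.character(n),
    "0" = cos(z),
    "1" = cos(z) / z + sin(z),
    "2" = (3 / z^2 - 1) * cos(z) + (3 / z) * sin(z),
    "3" = (15 / z^3 - 6 / z) * cos(z) + (15 / z^2 - 1) * sin(z),
    "4" = (105 / z^4 - 45 / z^2 + 1) * cos(z) +
      (105 / z^3 - 10 / z) * sin(z),
    stop("chi_closed only implemented for n <= 4"))
}

dpsi_closed <- function(n, z) psi_closed(n - 1, z) - (n / z) * psi_closed(n, z)
dchi_closed <- function(n, z) chi_closed(n - 1, z) - (n / z) * chi_closed(n, z)
xi_closed <- function(n, z) psi_closed(n, z) - 1i * chi_closed(n, z)
dxi_closed <- function(n, z) dpsi_closed(n, z) - 1i * dchi_closed(n, z)

# Direct textbook evaluation of solid-sphere Mie coefficients, n <= 4.
mie_solid_oracle <- function(x, m, n_max = 4L) {
  ns <- seq_len(n_max)
  a <- vapply(ns, function(n) {
    (m * psi_closed(n, m * x) * dpsi_closed(n, x) -
       psi_closed(n, x) * dpsi_closed(n, m * x)) /
      (m * psi_closed(n, m * x) * dxi_closed(n, x) -
         xi_closed(n, x) * dpsi_closed(n, m * x))
  }, complex(1))
  b <- vapply(ns, function(n) {
    (psi_closed(n, m * x) * dpsi_closed(n, x) -
       m * psi_closed(n, x) * dpsi_closed(n, m * x)) /
      (psi_closed(n, m * x) * dxi_closed(n, x) -
         m * xi_closed(n, x) * dpsi_closed(n, m * x))
  }, complex(1))
  tibble::tibble(n = ns, a = a, b = b)
}

# Quasi-static (dipole-limit) cross-sections of a coated sphere from the
# classical core-shell polarizability; radii in nm, absolute indices.
coated_quasistatic_oracle <- function(r_core_nm, r_outer_nm, m_core_abs,
                                      m_shell_abs, medium_index,
                                      wavelength_nm) {
  e1 <- m_core_abs^2
  e2 <- m_shell_abs^2
  em <- medium_index^2
  f <- (r_core_nm / r_outer_nm)^3
  alpha <- 4 * pi * r_outer_nm^3 *
    ((e2 - em) * (e1 + 2 * e2) + f * (e1 - e2) * (em + 2 * e2)) /
    ((e2 + 2 * em) * (e1 + 2 * e2) + f * (2 * e2 - 2 * em) * (e1 - e2))
  k <- 2 * pi * medium_index / wavelength_nm
  list(C_abs = k * Im(alpha), C_sca = k^4 / (6 * pi) * Mod(alpha)^2)
}

# Rayleigh (dipole) absorption of a solid sphere.
solid_rayleigh_oracle <- function(r_nm, m_abs, medium_index,
                                  wavelength_nm) {
  e <- (m_abs / medium_index)^2
  alpha <- 4 * pi * r_nm^3 * (e - 1) / (e + 2)
  k <- 2 * pi * medium_index / wavelength_nm
  k * Im(alpha)
}

# Bilinear rotation of an image about a center, for rotation-invariance
# checks. Pixels sampled from outside the source grid keep `fill`.
rotate_image <- function(img, angle_rad, center, fill = NULL) {
  d <- dim(img)
  fill <- fill %||% median(img)
  xs <- col(img) - center[1L]
  ys <- row(img) - center[2L]
  xr <- cos(angle_rad) * xs + sin(angle_rad) * ys + center[1L]
  yr <- -sin(angle_rad) * xs + cos(angle_rad) * ys + center[2L]
  x0 <- floor(xr); y0 <- floor(yr)
  fx <- xr - x0; fy <- yr - y0
  out <- matrix(fill, d[1L], d[2L])
  ok <- x0 >= 1 & x0 + 1 <= d[2L] & y0 >= 1 & y0 + 1 <= d[1L]
  idx <- function(y, x) (x - 1L) * d[1L] + y
  v <- img[idx(y0[ok], x0[ok])] * (1 - fx[ok]) * (1 - fy[ok]) +
    img[idx(y0[ok], x0[ok] + 1L)] * fx[ok] * (1 - fy[ok]) +
    img[idx(y0[ok] + 1L, x0[ok])] * (1 - fx[ok]) * fy[ok] +
    img[idx(y0[ok] + 1L, x0[ok] + 1L)] * fx[ok] * fy[ok]
  out[ok] <- v
  out
}

# Frame with a Gaussian reflection spot, for centroid tests.
gaussian_spot_frame <- function(center, dim_px = 64L, sigma_px = 2,
                                pixel_size_um = 0.08) {
  xs <- seq_len(dim_px)
  gx <- exp(-(xs - center[1L])^2 / (2 * sigma_px^2))
  gy <- exp(-(xs - center[2L])^2 / (2 * sigma_px^2))
  spot <- 500 * outer(gy, gx)
  microscopy_frame(fluorescence = spot + 10, reflection = spot + 10,
                   pixel_size_um = pixel_size_um)
}

# Manually assembled radial profile (for threshold-crossing tests).
manual_profile <- function(r_um, mean_intensity) {
  out <- tibble::tibble(r_um = r_um, mean_intensity = mean_intensity,
                        n_px = rep(8L, length(r_um)))
  structure(out, bin_width_um = diff(r_um)[1L],
            class = c("radial_profile", class(out)))
}
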