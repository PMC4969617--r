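#' Cross-section spectrum of a particle
#'
#' Computes absorption, scattering and extinction cross-sections on a
#' wavelength grid for a [particle_spec()] immersed in a homogeneous
#' medium (default water, n = 1.33). The glass substrate of the
#' single-particle experiment is deliberately not modelled; the
#' homogeneous-medium spectrum is the documented approximation.
#'
#' @param particle A [particle_spec()].
#' @param medium_index Real medium index; default 1.33 (water).
#' @param wavelengths_nm Wavelength grid in nm; default 400--1100 nm in
#'   1 nm steps.
#' @param n_max Optional truncation override passed to the Mie layer.
#' @return A `cross_section_spectrum`: a tibble with columns
#'   `wavelength_nm`, `C_abs_nm2`, `C_sca_nm2`, `C_ext_nm2`, carrying the
#'   particle name and medium index as attributes.
#' @export
#' @examples
#' \donttest{
#' sp <- spectrum(particle_solid_gold(80), wavelengths_nm = seq(500, 600, 5))
#' peak_wavelength(sp, "abs")
#' }
spectrum <- function(particle, medium_index = 1.33,
                     wavelengths_nm = seq(400, 1100, by = 1),
                     n_max = NULL) {
  stopifnot(inherits(particle, "particle_spec"),
            length(wavelengths_nm) >= 1L, all(is.finite(wavelengths_nm)))
  rows <- purrr::map(wavelengths_nm, function(wl) {
    cs <- cross_sections(
      mie_coefficients(particle, wl, medium_index, n_max = n_max),
      wl, medium_index)
    dplyr::mutate(cs, wavelength_nm = wl, .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  structure(out,
            particle = particle$name,
            medium_index = medium_index,
            class = c("cross_section_spectrum", class(out)))
}

#' Peak wavelength of a spectrum channel
#'
#' Finds the grid maximum of the requested channel and refines it by
#' fitting a parabola through the three surrounding points. A maximum on
#' the grid boundary cannot be refined and is flagged.
#'
#' @param spectrum A [spectrum()] result (or any tibble with a
#'   `wavelength_nm` column and the channel column).
#' @param channel `"abs"` or `"ext"`.
#' @return One-row tibble: `channel`, `peak_nm`, `peak_value_nm2`,
#'   `on_boundary`.
#' @export
peak_wavelength <- function(spectrum, channel = c("abs", "ext")) {
  channel <- match.arg(channel)
  col <- c(abs = "C_abs_nm2", ext = "C_ext_nm2")[[channel]]
  stopifnot(nrow(spectrum) >= 1L, col %in% names(spectrum))
  wl <- spectrum$wavelength_nm
  y <- spectrum[[col]]
  i <- which.max(y)
  on_boundary <- i == 1L || i == length(y)
  if (on_boundary) {
    warn("spectrum maximum lies on the grid boundary; peak not refined")
    peak <- wl[i]
    value <- y[i]
  } else {
    # parabola through (wl[i-1..i+1], y[i-1..i+1]); vertex in closed form
    x1 <- wl[i - 1L]; x2 <- wl[i]; x3 <- wl[i + 1L]
    y1 <- y[i - 1L];  y2 <- y[i];  y3 <- y[i + 1L]
    denom <- (x1 - x2) * (x1 - x3) * (x2 - x3)
    a <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / denom
    b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / denom
    if (a < 0) {
      peak <- -b / (2 * a)
      cc <- y2 - a * x2^2 - b * x2
      value <- a * peak^2 + b * peak + cc
    } else {                       # flat/degenerate: keep the grid point
      peak <- x2
      value <- y2
    }
  }
  tibble::tibble(channel = channel, peak_nm = peak,
                 peak_value_nm2 = value, on_boundary = on_boundary)
}

#' @export
print.cross_section_spectrum <- function(x, ...) {
  cat("<cross_section_spectrum> ", attr(x, "particle"),
      " in medium n = ", attr(x, "medium_index"), "\n", sep = "")
  NextMethod()
}

#' Plot a cross-section spectrum
#'
#' @param object A [spectrum()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cross_section_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("C_abs_nm2", "C_sca_nm2", "C_ext_nm2"),
    names_to = "channel", values_to = "cross_section_nm2")
  long$channel <- factor(long$channel,
                         levels = c("C_abs_nm2", "C_sca_nm2", "C_ext_nm2"),
                         labels = c("absorption", "scattering", "extinction"))
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm,
                                     .data$cross_section_nm2,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = expression("cross-section (nm"^2 * ")"),
                  colour = NULL,
                  title = attr(object, "particle")) +
    ggplot2::theme_minimal()
}
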