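#' Optical materials
#'
#' An `optical_material` holds a tabulated complex refractive index
#' \eqn{m(\lambda) = n(\lambda) + i\,k(\lambda)} on a strictly increasing
#' wavelength grid. Queries between tabulated wavelengths are linearly
#' interpolated on both parts; queries outside the tabulated range are
#' errors, never extrapolations.
#'
#' @param name Label used in error messages and printouts.
#' @param table Data frame with columns `wavelength_nm`, `n`, `k`.
#'
#' @return An `optical_material` object (a tibble of the table with
#'   attributes), usable with [interpolate_index()].
#' @export
#' @examples
#' au <- material_gold()
#' interpolate_index(au, 1064)
optical_material <- function(name, table) {
  stopifnot(is.character(name), length(name) == 1L)
  table <- tibble::as_tibble(table)
  required <- c("wavelength_nm", "n", "k")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0L) {
    abort(paste0("material table for '", name, "' lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  table <- table[required]
  if (nrow(table) < 2L) {
    abort(paste0("material '", name, "' needs at least two tabulated rows"))
  }
  if (any(!is.finite(table$wavelength_nm)) || any(!is.finite(table$n)) ||
      any(!is.finite(table$k))) {
    abort(paste0("material '", name, "' contains non-finite entries"))
  }
  if (any(diff(table$wavelength_nm) <= 0)) {
    abort(paste0("material '", name,
                 "' wavelengths must be strictly increasing"))
  }
  if (any(table$k < 0)) {
    abort(paste0("material '", name, "' has negative k (gain media are ",
                 "not supported)"))
  }
  structure(table, name = name,
            class = c("optical_material", class(table)))
}

#' Constant-index material over a wavelength band
#'
#' Convenience constructor for dispersionless materials (silica, water)
#' represented as a two-row table spanning `range_nm`.
#'
#' @param name Label.
#' @param n,k Real and imaginary index parts.
#' @param range_nm Two-element wavelength coverage in nm.
#' @export
material_constant <- function(name, n, k = 0, range_nm = c(200, 2000)) {
  optical_material(name, tibble::tibble(
    wavelength_nm = sort(range_nm), n = c(n, n), k = c(k, k)))
}

#' @describeIn material_constant Gold, Johnson & Christy tabulation
#'   packaged with `nanoheat` (covers 381--1216 nm).
#' @export
material_gold <- function() {
  path <- system.file("extdata", "gold_johnson_christy.csv",
                      package = "nanoheat", mustWork = TRUE)
  read_material_csv(path, name = "gold")
}

#' @describeIn material_constant Fused silica, n = 1.45 constant.
#' @export
material_silica <- function() material_constant("silica", 1.45)

#' @describeIn material_constant Water, n = 1.33 constant.
#' @export
material_water <- function() material_constant("water", 1.33)

#' Read a material table from CSV
#'
#' Expects the header `wavelength_nm,n,k`.
#'
#' @param path CSV file path.
#' @param name Material label; defaults to the file stem.
#' @return An [optical_material()].
#' @export
read_material_csv <- function(path, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  table <- readr::read_csv(path, show_col_types = FALSE)
  optical_material(name, table)
}

#' Interpolate a complex refractive index
#'
#' Linear interpolation of both the real and imaginary index parts at
#' `wavelength_nm`. Vectorised over wavelengths.
#'
#' @param material An [optical_material()].
#' @param wavelength_nm Query wavelength(s) in nm; must lie inside the
#'   tabulated range.
#' @return Complex vector `n + ik`, one element per query.
#' @export
interpolate_index <- function(material, wavelength_nm) {
  stopifnot(inherits(material, "optical_material"))
  if (any(!is.finite(wavelength_nm))) {
    abort("wavelength_nm must be finite")
  }
  wl <- material$wavelength_nm
  if (any(wavelength_nm < wl[1L] | wavelength_nm > wl[length(wl)])) {
    abort(sprintf(
      "wavelength outside tabulated range [%.6g, %.6g] nm for material '%s'",
      wl[1L], wl[length(wl)], attr(material, "name")))
  }
  n <- stats::approx(wl, material$n, xout = wavelength_nm)$y
  k <- stats::approx(wl, material$k, xout = wavelength_nm)$y
  complex(real = n, imaginary = k)
}
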