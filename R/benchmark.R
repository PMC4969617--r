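#' Benchmark particle specs as photothermal heaters
#'
#' The end-to-end comparison the platform exists for: for every
#' candidate particle it computes the theoretical absorption
#' cross-section at the wavelengths of interest, the predicted surface
#' temperature increase at the requested intensities (via
#' \eqn{C = C_{abs}/(4\pi k)} and \eqn{\Delta T_P = C I / R}), and --
#' when single-particle footprint measurements are supplied -- the
#' experimental cross-section inferred from the melting footprints.
#' Particles are ranked by theoretical C_abs at the therapy wavelength.
#'
#' @param particles List of [particle_spec()] (or a single one).
#' @param wavelengths_nm Wavelengths of interest, nm; must include
#'   `therapy_wavelength_nm`.
#' @param therapy_wavelength_nm Ranking wavelength; default 807 nm.
#' @param medium_index Medium refractive index; default 1.33.
#' @param intensities_W_cm2 Optional intensities for surface-temperature
#'   predictions.
#' @param footprints Optional tibble of footprint measurements with
#'   columns `particle`, `D_m_um`, `intensity_W_cm2` (particle values
#'   must match particle names).
#' @param env A [thermal_environment()].
#' @return A `nanoheat_benchmark` list: `ranking` (tibble, one row per
#'   particle, ranked), `cross_sections` (per wavelength),
#'   `predictions` (per intensity, if requested).
#' @export
#' @examples
#' \donttest{
#' bench <- run_benchmark(list(particle_nanoshell(),
#'                             particle_solid_gold(150)),
#'                        wavelengths_nm = c(807, 1064))
#' bench$ranking
#' }
run_benchmark <- function(particles,
                          wavelengths_nm = c(807, 1064),
                          therapy_wavelength_nm = 807,
                          medium_index = 1.33,
                          intensities_W_cm2 = NULL,
                          footprints = NULL,
                          env = thermal_environment()) {
  if (inherits(particles, "particle_spec")) particles <- list(particles)
  stopifnot(length(particles) >= 1L,
            all(purrr::map_lgl(particles, inherits, "particle_spec")),
            therapy_wavelength_nm %in% wavelengths_nm)
  names(particles) <- purrr::map_chr(particles, "name")

  cs <- purrr::map(particles, function(p) {
    purrr::map(wavelengths_nm, function(wl) {
      out <- cross_sections(
        mie_coefficients(p, wl, medium_index), wl, medium_index)
      dplyr::mutate(out, particle = p$name, wavelength_nm = wl,
                    .before = 1L)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  ranking <- cs |>
    dplyr::filter(.data$wavelength_nm == therapy_wavelength_nm) |>
    dplyr::arrange(dplyr::desc(.data$C_abs_nm2)) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  R_nm = purrr::map_dbl(
                    .data$particle,
                    function(nm) particles[[nm]]$outer_radius_nm)) |>
    dplyr::select("rank", "particle", "wavelength_nm", "C_abs_nm2",
                  "C_sca_nm2", "C_ext_nm2", "R_nm")

  predictions <- NULL
  if (!is.null(intensities_W_cm2)) {
    predictions <- ranking |>
      tidyr::expand_grid(intensity_W_cm2 = intensities_W_cm2) |>
      dplyr::mutate(
        C_K_m3_W = .data$C_abs_nm2 * 1e-18 / (4 * pi * env$k),
        dT_surface_K = .data$C_K_m3_W * (.data$intensity_W_cm2 * 1e4) /
          (.data$R_nm * 1e-9),
        saturated = env$T_ambient_C + .data$dT_surface_K > 240) |>
      dplyr::select("particle", "intensity_W_cm2", "C_abs_nm2",
                    "dT_surface_K", "saturated")
  }

  experimental <- NULL
  if (!is.null(footprints)) {
    stopifnot(all(c("particle", "D_m_um", "intensity_W_cm2")
                  %in% names(footprints)))
    bad <- setdiff(unique(footprints$particle), names(particles))
    if (length(bad) > 0L) {
      abort(paste0("footprint rows reference unknown particle(s): ",
                   paste(bad, collapse = ", ")),
            class = "nanoheat_error_schema")
    }
    experimental <- footprints |>
      dplyr::mutate(R_nm = purrr::map_dbl(
        .data$particle, function(nm) particles[[nm]]$outer_radius_nm)) |>
      fit_C(env = env) |>
      dplyr::mutate(C_abs_exp_nm2 = cross_section_from_model(
        dplyr::pick(dplyr::everything()), env = env)) |>
      dplyr::group_by(.data$particle) |>
      dplyr::summarise(C_abs_exp_nm2 = mean(.data$C_abs_exp_nm2),
                       n_footprints = dplyr::n(), .groups = "drop")
    ranking <- dplyr::left_join(ranking, experimental, by = "particle")
  }

  structure(list(ranking = ranking, cross_sections = cs,
                 predictions = predictions,
                 therapy_wavelength_nm = therapy_wavelength_nm,
                 medium_index = medium_index),
            class = "nanoheat_benchmark")
}

#' @export
print.nanoheat_benchmark <- function(x, ...) {
  cat(sprintf(
    "<nanoheat_benchmark> %d particle(s), ranked by C_abs at %g nm\n",
    nrow(x$ranking), x$therapy_wavelength_nm))
  df <- as.data.frame(x$ranking)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write benchmark outputs
#'
#' `ranking.csv` and `cross_sections.csv` plus a short human-readable
#' `summary.txt` into `dir`. Output is byte-deterministic for a given
#' input (no timestamps).
#'
#' @param benchmark A [run_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "nanoheat_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(benchmark$ranking, file.path(dir, "ranking.csv"))
  readr::write_csv(benchmark$cross_sections,
                   file.path(dir, "cross_sections.csv"))
  if (!is.null(benchmark$predictions)) {
    readr::write_csv(benchmark$predictions,
                     file.path(dir, "predictions.csv"))
  }
  lines <- c(
    sprintf("Particle ranking by C_abs at %g nm (medium n = %g):",
            benchmark$therapy_wavelength_nm, benchmark$medium_index),
    sprintf("  %d. %s  C_abs = %.4g nm^2",
            benchmark$ranking$rank, benchmark$ranking$particle,
            benchmark$ranking$C_abs_nm2))
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
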