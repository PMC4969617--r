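#' Thermal environment of the supported-bilayer assay
#'
#' Holds the conductivities and temperatures entering the point-source
#' heating relation \eqn{\Delta T(D) = C I / D}. The combined
#' conductivity of the glass--water half-spaces is the simple average
#' `(k_glass + k_water)/2`.
#'
#' @param k_glass Glass thermal conductivity, W/(m K); default 1.1.
#' @param k_water Water thermal conductivity, W/(m K); default 0.61.
#' @param T_m_C Bilayer gel-to-fluid melting temperature, degrees C;
#'   default 33.8 (DC15PC).
#' @param T_ambient_C Ambient chamber temperature, degrees C; default
#'   26.7.
#' @return A `thermal_environment` list with the inputs plus the
#'   combined `k`.
#' @export
#' @examples
#' thermal_environment()
thermal_environment <- function(k_glass = 1.1, k_water = 0.61,
                                T_m_C = 33.8, T_ambient_C = 26.7) {
  stopifnot(k_glass > 0, k_water > 0,
            is.finite(T_m_C), is.finite(T_ambient_C))
  structure(
    list(k_glass = k_glass, k_water = k_water,
         k = (k_glass + k_water) / 2,
         T_m_C = T_m_C, T_ambient_C = T_ambient_C),
    class = "thermal_environment")
}

#' @export
print.thermal_environment <- function(x, ...) {
  cat("<thermal_environment>\n")
  cat(sprintf("  k = (%.3g + %.3g)/2 = %.4g W/(m K)\n",
              x$k_glass, x$k_water, x$k))
  cat(sprintf("  T_m = %.1f C, T_ambient = %.1f C\n", x$T_m_C, x$T_ambient_C))
  invisible(x)
}

#' Fit the heating constant C from melted footprints
#'
#' At the footprint boundary the bilayer temperature equals the melting
#' temperature, so \eqn{\Delta T(D_m) = T_m - T_{ambient}} and
#' \eqn{C = (T_m - T_{ambient}) D_m / I}. Vectorised over footprint
#' rows; returns one fitted model per row.
#'
#' @param footprints Data frame with columns `D_m_um` (footprint radius,
#'   micrometres) and `intensity_W_cm2` (laser intensity, W/cm2), e.g.
#'   from [analyze_frame()]. An optional `R_nm` column (or the `R_nm`
#'   argument) attaches the particle radius needed for surface
#'   temperatures.
#' @param env A [thermal_environment()].
#' @param R_nm Particle radius in nm, recycled across rows; overridden
#'   by a `R_nm` column if present.
#' @return Tibble: input identifiers plus `C_K_m3_W` (the constant, in
#'   K m^3/W), `R_nm`, and the environment as attribute
#'   (`heating_model` class rows usable by [surface_temperature()] etc.).
#' @export
#' @examples
#' fp <- tibble::tibble(D_m_um = 2.046, intensity_W_cm2 = 2.7e6)
#' fit_C(fp, thermal_environment(), R_nm = 75.65)
fit_C <- function(footprints, env = thermal_environment(), R_nm = NULL) {
  stopifnot(inherits(env, "thermal_environment"),
            all(c("D_m_um", "intensity_W_cm2") %in% names(footprints)))
  dT_m <- env$T_m_C - env$T_ambient_C
  if (dT_m <= 0) {
    abort("T_m must exceed T_ambient: no melting boundary can exist")
  }
  fp <- tibble::as_tibble(footprints)
  if (!is.null(R_nm) && !("R_nm" %in% names(fp))) fp$R_nm <- R_nm
  if (any(!is.finite(fp$D_m_um)) || any(fp$D_m_um <= 0)) {
    abort("D_m_um must be positive and finite")
  }
  if (any(!is.finite(fp$intensity_W_cm2)) || any(fp$intensity_W_cm2 <= 0)) {
    abort("intensity_W_cm2 must be positive and finite")
  }
  I_si <- fp$intensity_W_cm2 * 1e4          # W/m^2
  D_si <- fp$D_m_um * 1e-6                  # m
  out <- dplyr::mutate(fp, C_K_m3_W = dT_m * D_si / I_si)
  structure(out, env = env, class = c("heating_model", class(out)))
}

heating_env <- function(model, env) {
  env %||% attr(model, "env") %||% thermal_environment()
}

#' Temperature increase at distance D from the particle center
#'
#' Evaluates \eqn{\Delta T(D) = C I / D}, valid outside the particle
#' (`D >= R`). For `D < R` use [surface_temperature()].
#'
#' @param model A [fit_C()] result (or tibble with `C_K_m3_W`, `R_nm`).
#' @param intensity_W_cm2 Laser intensity in W/cm2.
#' @param D_um Distance from the particle center in micrometres.
#' @return Temperature increase in K (vector, one per model row).
#' @export
temperature_at <- function(model, intensity_W_cm2, D_um) {
  stopifnot("C_K_m3_W" %in% names(model),
            all(intensity_W_cm2 > 0), all(D_um > 0))
  if ("R_nm" %in% names(model) && any(!is.na(model$R_nm)) &&
      any(D_um * 1e3 < model$R_nm, na.rm = TRUE)) {
    abort("D lies inside the particle; use surface_temperature()")
  }
  model$C_K_m3_W * (intensity_W_cm2 * 1e4) / (D_um * 1e-6)
}

#' Particle surface temperature increase
#'
#' \eqn{\Delta T_P = C I / R}. Temperatures whose absolute value
#' `T_ambient + dT` exceeds `saturation_cap_C` are flagged: the linear
#' point-source model is an extrapolation beyond the regime in which the
#' proportionality has been observed (micro-bubble formation and similar
#' surface phenomena set in near 240 degrees C). Values are still
#' returned.
#'
#' @inheritParams temperature_at
#' @param env Optional [thermal_environment()] override (defaults to the
#'   one stored in `model`).
#' @param saturation_cap_C Absolute temperature cap in degrees C;
#'   default 240.
#' @return Tibble with `dT_surface_K`, `T_surface_C`, `saturated`.
#' @export
surface_temperature <- function(model, intensity_W_cm2, env = NULL,
                                saturation_cap_C = 240) {
  stopifnot(all(c("C_K_m3_W", "R_nm") %in% names(model)))
  if (any(!is.finite(intensity_W_cm2)) || any(intensity_W_cm2 <= 0)) {
    abort("intensity_W_cm2 must be positive")
  }
  env <- heating_env(model, env)
  dT <- model$C_K_m3_W * (intensity_W_cm2 * 1e4) / (model$R_nm * 1e-9)
  T_abs <- env$T_ambient_C + dT
  tibble::tibble(dT_surface_K = dT, T_surface_C = T_abs,
                 saturated = T_abs > saturation_cap_C)
}

#' Experimental absorption cross-section from the surface temperature
#'
#' The steady-state balance between absorbed power
#' \eqn{P = C_{abs} I} and conduction into the glass--water surroundings
#' gives \eqn{C_{abs} = 4\pi k R \Delta T_P / I}.
#'
#' @param dT_surface_K Surface temperature increase in K.
#' @param intensity_W_cm2 Laser intensity in W/cm2.
#' @param R_nm Particle radius in nm.
#' @param env A [thermal_environment()] (supplies the combined k).
#' @return Absorption cross-section in nm^2.
#' @export
#' @examples
#' absorption_cross_section(192, 2.7e6, 75.65, thermal_environment())
absorption_cross_section <- function(dT_surface_K, intensity_W_cm2, R_nm,
                                     env = thermal_environment()) {
  stopifnot(inherits(env, "thermal_environment"),
            all(dT_surface_K >= 0), all(intensity_W_cm2 > 0), all(R_nm > 0))
  C_abs_m2 <- 4 * pi * env$k * (R_nm * 1e-9) * dT_surface_K /
    (intensity_W_cm2 * 1e4)
  C_abs_m2 * 1e18
}

#' Experimental cross-section directly from a fitted heating model
#'
#' Algebraically, substituting \eqn{\Delta T_P = C I / R} into the
#' conduction balance collapses to \eqn{C_{abs} = 4\pi k C}, independent
#' of intensity and radius.
#'
#' @param model A [fit_C()] result.
#' @param env Optional environment override.
#' @return Vector of C_abs in nm^2, one per model row.
#' @export
cross_section_from_model <- function(model, env = NULL) {
  stopifnot("C_K_m3_W" %in% names(model))
  env <- heating_env(model, env)
  4 * pi * env$k * model$C_K_m3_W * 1e18
}

#' Fit the heat-conversion slope of a heating series
#'
#' Ordinary least squares of surface temperature increase against laser
#' power (or intensity) with the intercept fixed at zero, since the
#' point-source model forces \eqn{\Delta T(I = 0) = 0}. Points whose
#' absolute temperature reaches the saturation cap are excluded from the
#' fit and reported, never silently dropped. A free-intercept fit is
#' available for diagnostics.
#'
#' @param series Data frame with columns `power` (W, or intensity in the
#'   caller's units) and `dT_K`.
#' @param saturation_cap_C Absolute saturation cap in degrees C.
#' @param T_ambient_C Ambient used to convert `dT_K` to absolute.
#' @param free_intercept Fit an intercept as a diagnostic; default
#'   FALSE.
#' @return A `heating_fit` object; see [tidy.heating_fit()] and
#'   [glance.heating_fit()].
#' @export
#' @examples
#' s <- tibble::tibble(power = 1:5 * 1e-3, dT_K = 573.7 * 1:5 * 1e-3)
#' glance(fit_heating_slope(s))
fit_heating_slope <- function(series, saturation_cap_C = 240,
                              T_ambient_C = 26.7, free_intercept = FALSE) {
  stopifnot(all(c("power", "dT_K") %in% names(series)))
  series <- tibble::as_tibble(series)
  if (nrow(series) < 2L) abort("need at least two points to fit a slope")
  if (any(series$power <= 0)) abort("powers must be strictly positive")
  series$saturated <- (T_ambient_C + series$dT_K) >= saturation_cap_C
  used <- series[!series$saturated, ]
  if (nrow(used) == 0L) {
    abort("all points lie above the saturation cap; no linear regime to fit")
  }
  if (nrow(used) < 2L && !free_intercept) {
    warn("single unsaturated point: slope is a ratio, CI unavailable")
  }
  fml <- if (free_intercept) dT_K ~ power else dT_K ~ 0 + power
  fit <- lm(fml, data = used)
  structure(
    list(fit = fit, series = series, n_used = nrow(used),
         n_saturated = sum(series$saturated),
         free_intercept = free_intercept,
         saturation_cap_C = saturation_cap_C,
         T_ambient_C = T_ambient_C),
    class = "heating_fit")
}

#' @export
print.heating_fit <- function(x, ...) {
  g <- glance(x)
  cat("<heating_fit> slope =", format(g$slope_K_W, digits = 6),
      "K per unit power\n")
  cat(sprintf("  95%% CI [%.6g, %.6g]; %d points used, %d saturated\n",
              g$conf_low, g$conf_high, g$n_used, g$n_saturated))
  invisible(x)
}

#' Tidy a heating-slope fit
#'
#' @param x A [fit_heating_slope()] object.
#' @param conf_level Confidence level for the slope interval.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `term`, `estimate`,
#'   `std_error`, `conf_low`, `conf_high`.
#' @export
tidy.heating_fit <- function(x, conf_level = 0.95, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- suppressMessages(confint(x$fit, level = conf_level))
  tibble::tibble(term = rownames(sm),
                 estimate = sm[, "Estimate"],
                 std_error = sm[, "Std. Error"],
                 conf_low = ci[, 1L],
                 conf_high = ci[, 2L])
}

#' One-row summary of a heating-slope fit
#'
#' @inheritParams tidy.heating_fit
#' @return Tibble: `slope_K_W`, `std_error`, `conf_low`, `conf_high`,
#'   `n_used`, `n_saturated`, `free_intercept`.
#' @export
glance.heating_fit <- function(x, ...) {
  td <- tidy(x)
  slope <- td[td$term == "power", ]
  tibble::tibble(slope_K_W = slope$estimate,
                 std_error = slope$std_error,
                 conf_low = slope$conf_low,
                 conf_high = slope$conf_high,
                 n_used = x$n_used,
                 n_saturated = x$n_saturated,
                 free_intercept = x$free_intercept)
}

#' Plot a heating series and its zero-intercept fit
#'
#' @param object A [fit_heating_slope()] object.
#' @param ... Unused.
#' @return A ggplot; saturated points are marked.
#' @export
autoplot.heating_fit <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$series,
                  ggplot2::aes(.data$power, .data$dT_K,
                               shape = .data$saturated)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = g$slope_K_W, intercept = 0,
                         linetype = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(x = "laser power (W)",
                  y = expression(Delta * T[P] ~ "(K)"),
                  shape = "saturated") +
    ggplot2::theme_minimal()
}
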