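#' PET uptake volume
#'
#' A 3D grid of FDG uptake in %ID/g (percent injected dose per gram of
#' body weight) with its voxel dimensions and a timepoint label.
#'
#' @param uptake 3D numeric array of %ID/g values (finite, >= 0).
#' @param voxel_dims_mm Length-3 voxel edge lengths in mm.
#' @param timepoint Label, e.g. `"baseline"`, `"day0"`, `"day2"`.
#' @return A `pet_volume` list.
#' @export
pet_volume <- function(uptake, voxel_dims_mm = c(0.29, 0.29, 0.79),
                       timepoint = "baseline") {
  stopifnot(is.array(uptake), length(dim(uptake)) == 3L,
            length(voxel_dims_mm) == 3L)
  if (any(!is.finite(uptake)) || any(uptake < 0)) {
    abort("uptake must be finite and non-negative (%ID/g)",
          class = "nanoheat_error_validation")
  }
  if (any(voxel_dims_mm <= 0)) {
    abort("voxel dimensions must be positive",
          class = "nanoheat_error_validation")
  }
  structure(list(uptake = uptake,
                 voxel_dims_mm = as.numeric(voxel_dims_mm),
                 timepoint = timepoint),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> %s: %s voxels @ %s mm\n", x$timepoint,
              paste(dim(x$uptake), collapse = " x "),
              paste(signif(x$voxel_dims_mm, 3), collapse = " x ")))
  invisible(x)
}

check_roi <- function(volume, roi) {
  stopifnot(inherits(volume, "pet_volume"), is.array(roi),
            is.logical(roi))
  if (!identical(dim(roi), dim(volume$uptake))) {
    abort("ROI mask shape must match the uptake grid",
          class = "nanoheat_error_validation")
  }
  if (!any(roi)) {
    abort("ROI mask is empty", class = "nanoheat_error_validation")
  }
  invisible(TRUE)
}

#' ROI uptake statistics
#'
#' Mean, maximum and sample (n-1) standard deviation of %ID/g over the
#' ROI voxels.
#'
#' @param volume A [pet_volume()].
#' @param roi Logical array congruent with the uptake grid; must select
#'   at least one voxel.
#' @return One-row tibble: `timepoint`, `n_voxels`, `mean_IDg`,
#'   `max_IDg`, `sd_IDg`.
#' @export
uptake_stats <- function(volume, roi) {
  check_roi(volume, roi)
  vals <- volume$uptake[roi]
  tibble::tibble(timepoint = volume$timepoint,
                 n_voxels = length(vals),
                 mean_IDg = mean(vals),
                 max_IDg = max(vals),
                 sd_IDg = if (length(vals) > 1L) sd(vals) else 0)
}

#' Low-uptake volume statistic
#'
#' The early treatment-response statistic: the tumor volume whose
#' uptake is strictly below the ROI mean minus 3/2 standard deviations.
#' Ablated or necrotic tissue stops accumulating FDG, so this volume
#' grows after effective photothermal treatment while ROI mean and max
#' barely move.
#'
#' @inheritParams uptake_stats
#' @param sd_factor Multiplier on the standard deviation; default 1.5.
#' @return One-row `response_result` tibble: `timepoint`, `mean_IDg`,
#'   `max_IDg`, `sd_IDg`, `threshold_IDg`, `V_low_mm3`, `roi_volume_mm3`.
#' @export
low_uptake_volume <- function(volume, roi, sd_factor = 1.5) {
  stats <- uptake_stats(volume, roi)
  voxel_mm3 <- prod(volume$voxel_dims_mm)
  threshold <- stats$mean_IDg - sd_factor * stats$sd_IDg
  if (stats$sd_IDg == 0) {
    warn("degenerate uptake distribution (sd = 0); V_low is 0")
    n_low <- 0L
  } else {
    n_low <- sum(volume$uptake[roi] < threshold)
  }
  tibble::tibble(timepoint = stats$timepoint,
                 mean_IDg = stats$mean_IDg,
                 max_IDg = stats$max_IDg,
                 sd_IDg = stats$sd_IDg,
                 threshold_IDg = threshold,
                 V_low_mm3 = n_low * voxel_mm3,
                 roi_volume_mm3 = stats$n_voxels * voxel_mm3)
}

#' Relative change of the low-uptake volume versus baseline
#'
#' Each follow-up scan is normalised to the animal's own baseline:
#' `V_low(t) / V_low(baseline)`.
#'
#' @param result_t One-row [low_uptake_volume()] result at the
#'   follow-up timepoint.
#' @param result_baseline One-row baseline result; its `V_low_mm3` must
#'   be positive.
#' @return Dimensionless ratio.
#' @export
relative_change <- function(result_t, result_baseline) {
  stopifnot("V_low_mm3" %in% names(result_t),
            "V_low_mm3" %in% names(result_baseline))
  if (result_baseline$V_low_mm3 <= 0) {
    abort(paste0("baseline V_low is zero: the relative change is ",
                 "undefined; report absolute V_low instead"),
          class = "nanoheat_error_baseline")
  }
  result_t$V_low_mm3 / result_baseline$V_low_mm3
}

#' Descriptive cohort summary of relative changes
#'
#' Per-group mean and SD of per-animal relative changes; no hypothesis
#' testing. Groups with a single animal report SD = 0 and are flagged.
#'
#' @param changes Data frame with columns `group`, `animal`,
#'   `relative_change` (and optionally `timepoint`, kept as a grouping
#'   variable if present).
#' @return Tibble: one row per group (x timepoint), with `n`, `mean`,
#'   `sd`, `single_animal`.
#' @export
cohort_summary <- function(changes) {
  stopifnot(all(c("group", "relative_change") %in% names(changes)))
  keys <- intersect(c("group", "timepoint"), names(changes))
  changes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$relative_change),
      sd = if (dplyr::n() > 1L) sd(.data$relative_change) else 0,
      single_animal = dplyr::n() == 1L,
      .groups = "drop")
}

#' Percent injected dose per gram from raw activity
#'
#' `%ID/g = 100 * (activity concentration / injected dose) * body
#' weight`. Provided as an optional helper; scans are normally supplied
#' already calibrated.
#'
#' @param activity_conc Voxel activity concentration (e.g. Bq/mL,
#'   decay-corrected), array or vector.
#' @param injected_dose_Bq Injected dose in the same activity unit.
#' @param body_weight_g Body weight in grams.
#' @return %ID/g values, same shape as `activity_conc`.
#' @export
percent_id_per_g <- function(activity_conc, injected_dose_Bq,
                             body_weight_g) {
  stopifnot(injected_dose_Bq > 0, body_weight_g > 0)
  100 * (activity_conc / injected_dose_Bq) * body_weight_g
}

#' Plot per-animal relative-change trajectories
#'
#' @param changes Data frame as for [cohort_summary()], with a
#'   `timepoint` column.
#' @return A ggplot of per-animal trajectories with group means.
#' @export
plot_response_trajectories <- function(changes) {
  stopifnot(all(c("group", "animal", "timepoint", "relative_change")
                %in% names(changes)))
  ggplot2::ggplot(changes,
                  ggplot2::aes(.data$timepoint, .data$relative_change,
                               group = .data$animal)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$group),
                          fun = mean, geom = "line", linewidth = 1.2,
                          colour = "firebrick") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(y = expression(V[low] / V[low] ~ "(baseline)"),
                  x = NULL) +
    ggplot2::theme_minimal()
}
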