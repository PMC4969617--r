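#' Write / read a microscopy frame as TIFF + sidecar YAML
#'
#' The fluorescence (and optional reflection) channels are stored as
#' 32-bit float TIFF directories scaled into `[0, 1]`; the scale factor
#' and acquisition metadata go to a sidecar YAML next to the TIFF, so a
#' read restores intensities in the original units.
#'
#' @param frame A [microscopy_frame()].
#' @param path Output TIFF path; the sidecar is `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_frame_tiff <- function(frame, path) {
  stopifnot(inherits(frame, "microscopy_frame"))
  scale <- max(frame$fluorescence, frame$reflection, 1)
  imgs <- list(frame$fluorescence / scale)
  if (!is.null(frame$reflection)) {
    imgs <- c(imgs, list(frame$reflection / scale))
  }
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = frame$pixel_size_um,
               intensity_W_cm2 = frame$intensity_W_cm2,
               T_ambient_C = frame$T_ambient_C,
               intensity_scale = scale,
               channels = if (is.null(frame$reflection)) {
                 "fluorescence"
               } else c("fluorescence", "reflection"))
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_frame_tiff
#' @param meta Optional metadata list or sidecar YAML path; defaults to
#'   `<path>.yaml`.
#' @return For `read_frame_tiff()`, a [microscopy_frame()].
#' @export
read_frame_tiff <- function(path, meta = NULL) {
  if (is.null(meta)) meta <- paste0(path, ".yaml")
  if (is.character(meta)) {
    if (!file.exists(meta)) {
      abort(paste0("missing frame metadata: expected sidecar '", meta,
                   "' with pixel_size_um"),
            class = "nanoheat_error_schema")
    }
    meta <- yaml::read_yaml(meta)
  }
  for (field in c("pixel_size_um")) {
    if (is.null(meta[[field]])) {
      abort(paste0("frame metadata lacks required field '", field, "'"),
            class = "nanoheat_error_schema")
    }
  }
  imgs <- tiff::readTIFF(path, all = TRUE)
  scale <- meta$intensity_scale %||% 1
  fl <- imgs[[1L]] * scale
  rf <- if (length(imgs) > 1L) imgs[[2L]] * scale
  microscopy_frame(fl, reflection = rf,
                   pixel_size_um = meta$pixel_size_um,
                   intensity_W_cm2 = meta$intensity_W_cm2 %||% NA_real_,
                   T_ambient_C = meta$T_ambient_C %||% 26.7)
}

#' Write / read a PET volume as NIfTI
#'
#' Voxel dimensions travel in the NIfTI header (`pixdim`); the affine is
#' diagonal in those dimensions.
#'
#' @param volume A [pet_volume()] (or, for masks, a logical array via
#'   `write_roi_nifti()`).
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_pet_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(volume$uptake)
  RNifti::pixdim(img) <- volume$voxel_dims_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_pet_nifti
#' @param timepoint Timepoint label to attach on read.
#' @return For `read_pet_nifti()`, a [pet_volume()] with voxel
#'   dimensions from the header.
#' @export
read_pet_nifti <- function(path, timepoint = "baseline") {
  img <- RNifti::readNifti(path)
  dims <- RNifti::pixdim(img)
  pet_volume(array(as.numeric(img), dim = dim(img)),
             voxel_dims_mm = dims[seq_len(3L)], timepoint = timepoint)
}

#' @rdname write_pet_nifti
#' @param roi Logical 3D array.
#' @param voxel_dims_mm Voxel dimensions for the mask header.
#' @export
write_roi_nifti <- function(roi, path, voxel_dims_mm = c(0.29, 0.29, 0.79)) {
  stopifnot(is.array(roi), is.logical(roi))
  img <- RNifti::asNifti(array(as.integer(roi), dim = dim(roi)))
  RNifti::pixdim(img) <- voxel_dims_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_pet_nifti
#' @export
read_roi_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0, dim = dim(img))
}

#' Read / write footprint measurement tables
#'
#' The footprint CSV schema is one row per analysed frame with columns
#' `D_m_um` and `intensity_W_cm2` (plus whatever identifiers the caller
#' carries). A missing required column is a schema error naming it.
#'
#' @param path CSV path.
#' @return Tibble of footprint measurements.
#' @export
read_footprints_csv <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("D_m_um", "intensity_W_cm2")
  missing <- setdiff(required, names(tb))
  if (length(missing) > 0L) {
    abort(paste0("footprint CSV '", basename(path),
                 "' lacks required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "nanoheat_error_schema")
  }
  tb
}

#' @rdname read_footprints_csv
#' @param footprints Tibble to write.
#' @export
write_footprints_csv <- function(footprints, path) {
  readr::write_csv(footprints, path)
  invisible(path)
}

#' Read a particle specification from YAML
#'
#' Schema: `kind` (`solid`/`core_shell`), `outer_radius_nm`, optional
#' `core_radius_nm`, `shell_material` / `core_material` (one of
#' `gold`, `silica`, `water`, or a path to a `wavelength_nm,n,k` CSV),
#' optional `name`. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A [particle_spec()].
#' @export
read_particle_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("kind", "outer_radius_nm", "core_radius_nm",
             "shell_material", "core_material", "name")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown key(s) in particle YAML '", basename(path),
                 "': ", paste(unknown, collapse = ", ")),
          class = "nanoheat_error_schema")
  }
  for (field in c("kind", "outer_radius_nm", "shell_material")) {
    if (is.null(cfg[[field]])) {
      abort(paste0("particle YAML lacks required field '", field, "'"),
            class = "nanoheat_error_schema")
    }
  }
  resolve <- function(ref) {
    if (is.null(ref)) return(NULL)
    switch(ref,
           gold = material_gold(),
           silica = material_silica(),
           water = material_water(),
           read_material_csv(ref))
  }
  particle_spec(kind = cfg$kind,
                outer_radius_nm = cfg$outer_radius_nm,
                core_radius_nm = cfg$core_radius_nm,
                shell_material = resolve(cfg$shell_material),
                core_material = resolve(cfg$core_material),
                name = cfg$name)
}

#' Read thermal-environment constants from YAML
#'
#' Recognised keys: `k_glass`, `k_water`, `T_m_C`, `T_ambient_C`
#' (missing keys keep the defaults of [thermal_environment()]).
#'
#' @param path YAML file.
#' @return A [thermal_environment()].
#' @export
read_environment_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("k_glass", "k_water", "T_m_C", "T_ambient_C")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown key(s) in environment YAML: ",
                 paste(unknown, collapse = ", ")),
          class = "nanoheat_error_schema")
  }
  defaults <- formals(thermal_environment)
  args <- utils::modifyList(lapply(defaults, eval), cfg)
  do.call(thermal_environment, args)
}
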