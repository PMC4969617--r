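#' Particle specifications
#'
#' A `particle_spec` describes either a solid sphere or a core--shell
#' (coated) sphere together with its material assignment. Radii are in
#' nanometres.
#'
#' @param kind `"solid"` or `"core_shell"`.
#' @param outer_radius_nm Outer (total) radius in nm; must be positive.
#' @param core_radius_nm Core radius in nm (core--shell only); must
#'   satisfy `0 < core_radius_nm < outer_radius_nm`.
#' @param shell_material [optical_material()] of the sphere (solid) or of
#'   the shell (core--shell).
#' @param core_material [optical_material()] of the core (core--shell
#'   only).
#' @param name Optional label for reports.
#'
#' @return A `particle_spec` object.
#' @export
#' @examples
#' particle_nanoshell()
#' particle_solid_gold(diameter_nm = 80)
particle_spec <- function(kind = c("solid", "core_shell"),
                          outer_radius_nm,
                          shell_material,
                          core_radius_nm = NULL,
                          core_material = NULL,
                          name = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(outer_radius_nm), length(outer_radius_nm) == 1L)
  if (!is.finite(outer_radius_nm) || outer_radius_nm <= 0) {
    abort("outer_radius_nm must be positive and finite")
  }
  stopifnot(inherits(shell_material, "optical_material"))
  if (kind == "core_shell") {
    if (is.null(core_radius_nm) || is.null(core_material)) {
      abort("core_shell particles need core_radius_nm and core_material")
    }
    stopifnot(inherits(core_material, "optical_material"))
    if (!is.finite(core_radius_nm) || core_radius_nm <= 0 ||
        core_radius_nm >= outer_radius_nm) {
      abort("core_radius_nm must satisfy 0 < core < outer radius")
    }
  } else {
    core_radius_nm <- NULL
    core_material <- NULL
  }
  structure(
    list(kind = kind,
         outer_radius_nm = outer_radius_nm,
         core_radius_nm = core_radius_nm,
         shell_material = shell_material,
         core_material = core_material,
         name = name %||% default_particle_name(kind, outer_radius_nm)),
    class = "particle_spec")
}

default_particle_name <- function(kind, outer_radius_nm) {
  sprintf("%s_%gnm", kind, 2 * outer_radius_nm)
}

#' @describeIn particle_spec The silica--gold nanoshell studied here:
#'   120 nm silica core diameter, 150 nm total diameter (15 nm gold
#'   shell).
#' @export
particle_nanoshell <- function() {
  particle_spec("core_shell",
                outer_radius_nm = 75,
                core_radius_nm = 60,
                shell_material = material_gold(),
                core_material = material_silica(),
                name = "AuNS_150nm")
}

#' @describeIn particle_spec Solid gold sphere of the given diameter.
#' @param diameter_nm Diameter in nm for [particle_solid_gold()].
#' @export
particle_solid_gold <- function(diameter_nm = 150) {
  particle_spec("solid",
                outer_radius_nm = diameter_nm / 2,
                shell_material = material_gold(),
                name = sprintf("AuNP_%gnm", diameter_nm))
}

#' @export
print.particle_spec <- function(x, ...) {
  cat("<particle_spec> ", x$name, "\n", sep = "")
  cat("  kind:         ", x$kind, "\n", sep = "")
  cat("  outer radius: ", x$outer_radius_nm, " nm\n", sep = "")
  if (x$kind == "core_shell") {
    cat("  core radius:  ", x$core_radius_nm, " nm (",
        attr(x$core_material, "name"), " core, ",
        attr(x$shell_material, "name"), " shell)\n", sep = "")
  } else {
    cat("  material:     ", attr(x$shell_material, "name"), "\n", sep = "")
  }
  invisible(x)
}
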