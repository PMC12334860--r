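#' Convergent-lens beam specification
#'
#' Geometric and dosimetric parameters of the convergent, hollow,
#' quasi-monoenergetic kV beam. The focal volume is described by its
#' lateral and longitudinal FWHM in water; the entrance radiation arrives
#' through a hollow conical shell between the inner and outer half-angles,
#' converging on the focus.
#'
#' @param fwhm_lateral focal-volume FWHM perpendicular to the beam axis, mm.
#' @param fwhm_longitudinal focal-volume FWHM along the beam axis, mm.
#' @param energy photon energy, keV.
#' @param cone_outer_half_angle,cone_inner_half_angle half-angles (degrees)
#'   bounding the hollow cone shell; `0 < inner < outer < 90`.
#' @param source_focus_distance distance from the treatment-head exit to
#'   the focus, mm.
#' @param max_depth maximum water-equivalent depth (mm) of the focus below
#'   the body surface for a deliverable beam; 80 mm by default.
#' @param peak_to_entrance_ratio ratio (>1) of the focal peak dose to the
#'   entrance dose on the cone shell.
#' @param mu_water linear attenuation coefficient of water at `energy`,
#'   per mm; default 0.0206 /mm at 60 keV.
#' @return An object of class `lens_spec`.
#' @seealso [builtin_lens()] for the two prototype lenses.
#' @export
lens_spec <- function(fwhm_lateral, fwhm_longitudinal, energy = 60,
                      cone_outer_half_angle = 25, cone_inner_half_angle = 20,
                      source_focus_distance = 300, max_depth = 80,
                      peak_to_entrance_ratio = 20, mu_water = 0.0206) {
  for (nm in c("fwhm_lateral", "fwhm_longitudinal", "energy",
               "cone_outer_half_angle", "cone_inner_half_angle",
               "source_focus_distance", "max_depth",
               "peak_to_entrance_ratio", "mu_water")) {
    if (!is_number(get(nm)))
      clrt_abort(sprintf("%s must be a finite number", nm),
                 "clrt_invalid_argument")
  }
  if (fwhm_lateral <= 0 || fwhm_longitudinal <= 0)
    clrt_abort("focal FWHMs must be positive", "clrt_invalid_argument")
  if (!(cone_inner_half_angle > 0 &&
        cone_inner_half_angle < cone_outer_half_angle &&
        cone_outer_half_angle < 90))
    clrt_abort("need 0 < inner half-angle < outer half-angle < 90 degrees",
               "clrt_invalid_argument")
  if (peak_to_entrance_ratio <= 1)
    clrt_abort("peak_to_entrance_ratio must exceed 1", "clrt_invalid_argument")
  structure(
    list(energy = energy, fwhm_lateral = fwhm_lateral,
         fwhm_longitudinal = fwhm_longitudinal,
         cone_outer_half_angle = cone_outer_half_angle,
         cone_inner_half_angle = cone_inner_half_angle,
         source_focus_distance = source_focus_distance,
         max_depth = max_depth,
         peak_to_entrance_ratio = peak_to_entrance_ratio,
         mu_water = mu_water),
    class = "lens_spec"
  )
}

#' @export
print.lens_spec <- function(x, ...) {
  cat(sprintf("<lens_spec> %g keV, focal FWHM %g mm (lateral) x %g mm (longitudinal)\n",
              x$energy, x$fwhm_lateral, x$fwhm_longitudinal))
  cat(sprintf("  cone shell %g-%g deg, max depth %g mm, peak/entrance %g, mu_water %g /mm\n",
              x$cone_inner_half_angle, x$cone_outer_half_angle, x$max_depth,
              x$peak_to_entrance_ratio, x$mu_water))
  invisible(x)
}

#' Built-in prototype lenses
#'
#' The two prototype lens geometries: Lens A with an elongated focal
#' volume of 22.5 mm FWHM longitudinally and 3.4 mm laterally in water,
#' and Lens B with a more compact 10.8 mm x 1.3 mm focal volume. Both
#' operate at 60 keV.
#'
#' @param name `"A"` or `"B"`.
#' @return A [lens_spec()].
#' @examples
#' builtin_lens("A")$fwhm_lateral  # 3.4
#' @export
builtin_lens <- function(name) {
  if (!is.character(name) || length(name) != 1L)
    clrt_abort("lens name must be a single string", "clrt_invalid_argument")
  switch(name,
    A = lens_spec(fwhm_lateral = 3.4, fwhm_longitudinal = 22.5),
    B = lens_spec(fwhm_lateral = 1.3, fwhm_longitudinal = 10.8),
    clrt_abort(sprintf("unknown lens '%s' (available: A, B)", name),
               "clrt_unknown_lens")
  )
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
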