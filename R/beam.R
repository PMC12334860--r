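#' A single convergent beam
#'
#' One (focal target point, axis direction, weight) triple — the unit the
#' optimizer works in. The direction points from the entrance surface
#' toward the focus.
#'
#' @param target world position (mm) of the focal point.
#' @param direction beam axis; normalized if not already unit length.
#' @param weight non-negative beam weight.
#' @return An object of class `clrt_beam`.
#' @export
beam <- function(target, direction, weight = 1) {
  target <- vec3(target, "target")
  direction <- normalize3(direction)
  if (!is_number(weight) || weight < 0)
    clrt_abort("weight must be a non-negative number", "clrt_invalid_argument")
  structure(list(target = target, direction = direction, weight = weight),
            class = "clrt_beam")
}

#' Dose kernel of one convergent beam, per unit weight
#'
#' Computes the 3-D dose field of a single beam on the density grid. The
#' field is the sum of two components:
#'
#' * **Focal volume** — an anisotropic Gaussian aligned with the beam axis,
#'   with the lens's nominal lateral/longitudinal FWHMs in water, peak
#'   normalized to 1.0 per unit weight at the focus, truncated at 5 sigma.
#' * **Cone shell** — for voxels upstream of the focus whose polar angle
#'   from the axis lies between the inner and outer cone half-angles, the
#'   entrance-level dose `1/peak_to_entrance_ratio` times the geometric
#'   convergence factor `r_entry / max(r, r_floor)` (photon fluence
#'   concentrates as the annulus shrinks toward the focus; `r_floor`
#'   equals the longitudinal FWHM, where the shell meets the focal
#'   Gaussian) times water-equivalent attenuation
#'   `exp(-mu_water * radiological_depth)` along the ray from the body
#'   entry through the voxel to the focus.
#'
#' Dose is non-negative everywhere and exactly zero outside `BODY`; there
#' is no cone contribution downstream of the focus.
#'
#' @param lens a [lens_spec()].
#' @param bm a [beam()] (its weight is ignored; the kernel is per unit
#'   weight).
#' @param density density [voxel_grid()], g/cc.
#' @param body logical BODY mask with the grid's dims.
#' @param cone include the cone-shell component (`TRUE` by default;
#'   disable for focal-volume-only studies).
#' @return A dose [voxel_grid()] in Gy per unit weight.
#' @export
beam_dose <- function(lens, bm, density, body, cone = TRUE) {
  stopifnot(inherits(lens, "lens_spec"), inherits(density, "voxel_grid"))
  if (!inherits(bm, "clrt_beam"))
    clrt_abort("bm must be a clrt_beam", "clrt_invalid_argument")
  direction <- unit3(bm$direction)
  if (!identical(dim(body), as.integer(density$dims)))
    clrt_abort("body mask does not match the density grid", "clrt_invalid_argument")
  ti <- linear_index(density, world_to_index(density, bm$target))
  if (is.na(ti) || !body[ti])
    clrt_abort("beam target lies outside BODY", "clrt_invalid_geometry")

  d <- cpp_beam_dose(
    as.numeric(density$values), as.integer(body),
    as.integer(density$dims), density$spacing, density$origin,
    bm$target, direction,
    fwhm_to_sigma(lens$fwhm_lateral), fwhm_to_sigma(lens$fwhm_longitudinal),
    5.0,
    lens$cone_inner_half_angle * pi / 180,
    lens$cone_outer_half_angle * pi / 180,
    if (cone) 1 / lens$peak_to_entrance_ratio else 0,
    lens$mu_water, lens$fwhm_longitudinal
  )
  voxel_grid(array(d, density$dims), density$spacing, density$origin)
}

#' Full width at half maximum of a sampled dose profile
#'
#' Samples the dose field by trilinear interpolation along the line through
#' `center` with direction `axis`, in steps of `step` mm, and returns the
#' distance between the two half-maximum crossings (each located by linear
#' interpolation between the bracketing samples). `center` must be the
#' profile maximum along the line.
#'
#' @param dose a dose [voxel_grid()].
#' @param center world position (mm) of the profile peak.
#' @param axis unit vector of the profile line.
#' @param step sampling step, mm.
#' @return FWHM in mm.
#' @export
measure_profile_fwhm <- function(dose, center, axis, step = NULL) {
  center <- vec3(center, "center")
  axis <- normalize3(axis)
  if (is.null(step)) step <- min(dose$spacing) / 2
  if (!point_in_grid(dose, center))
    clrt_abort("center lies outside the dose grid", "clrt_invalid_argument")
  peak <- interp_trilinear(dose, rbind(center))
  if (peak <= 0)
    clrt_abort("profile peak is not positive at center", "clrt_invalid_argument")
  half <- peak / 2

  crossing <- function(sign) {
    # march outward until the profile drops below half maximum
    lo <- dose$origin - 0.5 * dose$spacing
    hi <- dose$origin + (dose$dims - 0.5) * dose$spacing
    tmax <- Inf
    for (a in 1:3) {
      da <- sign * axis[a]
      if (abs(da) > 1e-12) {
        t_edge <- if (da > 0) (hi[a] - center[a]) / da else (lo[a] - center[a]) / da
        tmax <- min(tmax, t_edge)
      }
    }
    ts <- seq(0, tmax, by = step)
    pts <- rbind(center)[rep(1, length(ts)), , drop = FALSE] +
      outer(ts, sign * axis)
    vals <- interp_trilinear(dose, pts)
    below <- which(vals < half)
    if (length(below) == 0)
      clrt_abort("profile never falls below half maximum within the grid",
                 "clrt_profile_unresolved")
    k <- below[1]
    if (k == 1) return(0)
    # linear interpolation between the bracketing samples
    t0 <- ts[k - 1]; v0 <- vals[k - 1]
    t1 <- ts[k];     v1 <- vals[k]
    t0 + (half - v0) / (v1 - v0) * (t1 - t0)
  }

  unname(crossing(+1) + crossing(-1))
}
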