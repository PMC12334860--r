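#' Cumulative dose-volume histogram
#'
#' Volume fraction of a structure receiving at least each dose level
#' (threshold rule `>=`). The curve starts at 1.0 for dose 0 and is
#' monotone non-increasing.
#'
#' @param dose dose [voxel_grid()], Gy.
#' @param mask logical structure mask (non-empty).
#' @param bin_width histogram bin width, Gy.
#' @param structure optional structure label stored on the result.
#' @return data.frame of class `dvh_curve` with columns `structure`,
#'   `dose_gy`, `volume_fraction`.
#' @export
compute_dvh <- function(dose, mask, bin_width, structure = "") {
  if (!any(mask)) clrt_abort("structure mask is empty", "clrt_invalid_argument")
  if (!is_number(bin_width) || bin_width <= 0)
    clrt_abort("bin_width must be > 0", "clrt_invalid_argument")
  d <- as.numeric(dose$values[mask])
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  # fraction of voxels at or above each edge, via the sorted dose vector
  ds <- sort(d)
  frac <- 1 - (findInterval(edges, ds, left.open = TRUE) / length(ds))
  out <- data.frame(structure = structure, dose_gy = edges,
                    volume_fraction = frac)
  class(out) <- c("dvh_curve", "data.frame")
  out
}

#' Volume receiving at least x percent of the prescription
#'
#' `Vx`: the volume (cc) of voxels whose dose is `>= x/100 * prescription`.
#' Restricted to a structure mask when one is given, otherwise taken over
#' the whole dose grid (the denominator convention of the conformity
#' index).
#'
#' @param dose dose [voxel_grid()], Gy.
#' @param x_percent threshold as a percentage of the prescription.
#' @param prescription prescription dose, Gy (> 0).
#' @param mask optional logical mask.
#' @return Volume in cc.
#' @export
volume_at_dose <- function(dose, x_percent, prescription, mask = NULL) {
  if (!is_number(prescription) || prescription <= 0)
    clrt_abort("prescription must be > 0", "clrt_invalid_argument")
  thr <- x_percent / 100 * prescription
  v <- if (is.null(mask)) as.numeric(dose$values) else
    as.numeric(dose$values[mask])
  sum(v >= thr) * voxel_volume_cc(dose)
}

#' Effective radius of a volume
#'
#' Radius (cm) of the sphere of equal volume: `(3V / 4 pi)^(1/3)`.
#'
#' @param volume_cc volume in cc (>= 0).
#' @return Radius in cm.
#' @export
effective_radius <- function(volume_cc) {
  if (!is.numeric(volume_cc) || any(volume_cc < 0))
    clrt_abort("volume must be >= 0", "clrt_invalid_argument")
  (3 * volume_cc / (4 * pi))^(1 / 3)
}

#' Plan quality indices
#'
#' The four standard indices, with their volume and effective-radius
#' intermediates:
#'
#' * `CI  = V100PTV / V100` — conformity index (prescription isodose
#'   inside the PTV);
#' * `TCI = V100PTV / VPTV` — target coverage index;
#' * `CN  = CI * TCI` — conformal number;
#' * `GI  = 50 / (R50eff - R100eff)` in %/cm — gradient index, with
#'   `Rxeff` the equivalent-sphere radius of the volume receiving at
#'   least x% of the prescription (whole grid). Equal radii report `Inf`.
#'
#' @param dose dose [voxel_grid()], Gy.
#' @param ptv logical PTV mask (non-empty).
#' @param prescription prescription dose, Gy (> 0).
#' @return An object of class `plan_indices`: list with `CI`, `TCI`, `CN`,
#'   `GI`, and intermediates `V100`, `V100PTV`, `VPTV` (cc), `R100eff`,
#'   `R50eff` (cm).
#' @export
plan_indices <- function(dose, ptv, prescription) {
  if (!any(ptv)) clrt_abort("PTV mask is empty", "clrt_invalid_argument")
  v100 <- volume_at_dose(dose, 100, prescription)
  if (v100 == 0)
    clrt_abort("no voxel reaches the prescription dose: CI undefined",
               "clrt_undefined_ci")
  v100ptv <- volume_at_dose(dose, 100, prescription, mask = ptv)
  vptv <- sum(ptv) * voxel_volume_cc(dose)
  v50 <- volume_at_dose(dose, 50, prescription)
  r100 <- effective_radius(v100)
  r50 <- effective_radius(v50)
  ci <- v100ptv / v100
  tci <- v100ptv / vptv
  gi <- if (r50 > r100) 50 / (r50 - r100) else Inf
  structure(list(CI = ci, TCI = tci, CN = ci * tci, GI = gi,
                 V100 = v100, V100PTV = v100ptv, VPTV = vptv,
                 R100eff = r100, R50eff = r50),
            class = "plan_indices")
}

#' @export
print.plan_indices <- function(x, ...) {
  cat("<plan_indices>\n")
  cat(sprintf("  CI  %.4f   TCI %.4f   CN %.4f   GI %.1f %%/cm\n",
              x$CI, x$TCI, x$CN, x$GI))
  cat(sprintf("  V100 %.4f cc (in PTV %.4f cc of %.4f cc), R100eff %.3f cm, R50eff %.3f cm\n",
              x$V100, x$V100PTV, x$VPTV, x$R100eff, x$R50eff))
  invisible(x)
}
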