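#' Synthetic planning phantoms
#'
#' Builds small CT-like density grids with a spherical planning target
#' volume (PTV) and at least one organ-at-risk (OAR) sphere, emulating the
#' planning situation of a deep-seated small target near critical normal
#' tissue. Four body compositions are available:
#'
#' * `water_box` — homogeneous water body (1.0 g/cc) with an air margin;
#' * `cranial`  — water body wrapped in a cortical-bone shell (1.85 g/cc);
#' * `thorax`   — water body with a lung block (0.26 g/cc) occupying the
#'   half-space on the +x side of the PTV, target sitting at its edge;
#' * `abdomen`  — water body with a bone (spine-like) cylinder along z on
#'   the -x side.
#'
#' Masks are binary, full-resolution rasters; a voxel belongs to a
#' structure when its *center* lies inside the analytic shape. A mild
#' seeded Gaussian density texture (sd 0.02 g/cc, clamped at 0) emulates CT
#' noise inside the body without touching the masks.
#'
#' @param kind one of `"water_box"`, `"cranial"`, `"thorax"`, `"abdomen"`.
#' @param dims integer triple, voxels per axis.
#' @param spacing positive mm triple.
#' @param ptv_radius PTV sphere radius, mm; must exceed `max(spacing)`.
#' @param ptv_center world position (mm) of the PTV center; default is the
#'   grid center.
#' @param oar_offset world offset (mm) of the OAR center from the PTV
#'   center; default `c(2.5, 0, 0) * ptv_radius`.
#' @param noise_sd standard deviation (g/cc) of the density texture.
#' @param seed integer seed making the texture reproducible.
#' @return A list with elements `grid` (density [voxel_grid()], g/cc) and
#'   `structures` (a [structure_set()] with `BODY`, `PTV`, `OAR`).
#' @examples
#' ph <- make_phantom("water_box", dims = c(40, 40, 40), spacing = c(2, 2, 2),
#'                    ptv_radius = 5)
#' structure_volume_cc(ph$structures, "PTV", ph$grid)
#' @export
make_phantom <- function(kind = c("water_box", "cranial", "thorax", "abdomen"),
                         dims, spacing, ptv_radius, ptv_center = NULL,
                         oar_offset = NULL, noise_sd = 0.02, seed = 1L) {
  kind <- match.arg(kind)
  dims <- as.integer(vec3(dims, "dims"))
  spacing <- vec3(spacing, "spacing")
  if (any(dims < 8L))
    clrt_abort("dims must be at least 8 voxels per axis", "clrt_invalid_argument")
  if (!is_number(ptv_radius) || ptv_radius <= max(spacing))
    clrt_abort("ptv_radius must exceed the largest spacing component",
               "clrt_invalid_argument")
  extent <- dims * spacing
  center <- (dims - 1) * spacing / 2   # grid center, origin at 0
  if (is.null(ptv_center)) ptv_center <- center
  ptv_center <- vec3(ptv_center, "ptv_center")
  if (is.null(oar_offset)) oar_offset <- c(2.5 * ptv_radius, 0, 0)
  oar_offset <- vec3(oar_offset, "oar_offset")

  grid0 <- voxel_grid(array(0, dims), spacing, origin = c(0, 0, 0))
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a])
  X <- array(rep(ax[[1]], times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)

  margin <- 2 * spacing  # air rind so every beam has a surface to enter
  body <- X >= margin[1] & X <= extent[1] - spacing[1] - margin[1] &
          Y >= margin[2] & Y <= extent[2] - spacing[2] - margin[2] &
          Z >= margin[3] & Z <= extent[3] - spacing[3] - margin[3]

  dens <- array(0, dims)
  dens[body] <- 1.0
  if (kind == "cranial") {
    shell_th <- max(4, 2 * max(spacing))
    inner <- X >= margin[1] + shell_th &
             X <= extent[1] - spacing[1] - margin[1] - shell_th &
             Y >= margin[2] + shell_th &
             Y <= extent[2] - spacing[2] - margin[2] - shell_th &
             Z >= margin[3] + shell_th &
             Z <= extent[3] - spacing[3] - margin[3] - shell_th
    dens[body & !inner] <- 1.85
  } else if (kind == "thorax") {
    lung <- body & X >= ptv_center[1] + ptv_radius
    dens[lung] <- 0.26
  } else if (kind == "abdomen") {
    bone_r <- 3 * max(spacing)
    bone_cx <- ptv_center[1] - 4 * ptv_radius
    bone <- body & ((X - bone_cx)^2 + (Y - ptv_center[2])^2 <= bone_r^2)
    dens[bone] <- 1.85
  }

  r2 <- (X - ptv_center[1])^2 + (Y - ptv_center[2])^2 + (Z - ptv_center[3])^2
  ptv <- r2 <= ptv_radius^2
  if (!any(ptv) || any(ptv & !body))
    clrt_abort("PTV lies (partly) outside BODY; move ptv_center or shrink ptv_radius",
               "clrt_invalid_geometry")

  oar_center <- ptv_center + oar_offset
  oar_r <- ptv_radius
  oar <- body &
    ((X - oar_center[1])^2 + (Y - oar_center[2])^2 + (Z - oar_center[3])^2
     <= oar_r^2)

  withr::with_seed(as.integer(seed), {
    noise <- array(rnorm(prod(dims), 0, noise_sd), dims)
  })
  dens[body] <- pmax(dens[body] + noise[body], 0.05)

  grid <- voxel_grid(dens, spacing, origin = c(0, 0, 0))
  structures <- structure_set(list(BODY = body, PTV = ptv, OAR = oar), grid)
  list(grid = grid, structures = structures)
}

#' Hounsfield units to mass density
#'
#' Piecewise-linear conversion with fixed knots -1000 HU -> 0.001 g/cc
#' (air), 0 HU -> 1.0 g/cc (water), 1000 HU -> 1.6 g/cc (bone-like), held
#' constant outside the outer knots. The map is monotone non-decreasing.
#'
#' @param hu_grid a [voxel_grid()] of Hounsfield units (values expected in
#'   \[-1024, 3000\]).
#' @return A [voxel_grid()] of mass density in g/cc on the same geometry.
#' @examples
#' g <- voxel_grid(array(c(-1000, 0, 500, 1000), c(4, 1, 1)), c(1, 1, 1))
#' hu_to_density(g)$values[, 1, 1]  # 0.001 1.0 1.3 1.6
#' @export
hu_to_density <- function(hu_grid) {
  knots_hu <- c(-1000, 0, 1000)
  knots_rho <- c(0.001, 1.0, 1.6)
  v <- approx(knots_hu, knots_rho, xout = as.numeric(hu_grid$values),
              rule = 2)$y
  voxel_grid(array(v, hu_grid$dims), hu_grid$spacing, hu_grid$origin)
}
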