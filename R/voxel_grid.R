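#' 3-D voxel grid
#'
#' The universal raster of the package: a 3-D scalar field (mass density in
#' g/cc, or dose in Gy, depending on context) with per-axis spacing and a
#' world origin. Voxel indices are 1-based in R; the world position of voxel
#' `(i, j, k)` is the *center* of that voxel,
#' `origin + (c(i, j, k) - 1) * spacing` (mm).
#'
#' @param values numeric 3-D array of voxel values.
#' @param spacing positive numeric triple, mm per axis.
#' @param origin numeric triple, world position (mm) of the center of voxel
#'   `(1, 1, 1)`.
#' @return An object of class `voxel_grid`: a list with elements `values`,
#'   `dims`, `spacing`, `origin`.
#' @examples
#' g <- voxel_grid(array(1, c(10, 10, 10)), spacing = c(2, 2, 2))
#' voxel_volume_cc(g)  # 0.008 cc
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    clrt_abort("values must be a 3-D array", "clrt_invalid_argument")
  spacing <- vec3(spacing, "spacing")
  if (any(spacing <= 0))
    clrt_abort("all spacing components must be > 0", "clrt_invalid_argument")
  origin <- vec3(origin, "origin")
  structure(
    list(values = values, dims = dim(values), spacing = spacing,
         origin = origin),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
    x$dims[1], x$dims[2], x$dims[3], x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume in cc
#'
#' @param grid a [voxel_grid()].
#' @return Volume of one voxel in cm^3 (`prod(spacing)/1000`).
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

#' World coordinates of voxel centers
#'
#' @param grid a [voxel_grid()].
#' @param index integer matrix (n x 3) or triple of 1-based voxel indices.
#' @return n x 3 matrix of world positions (mm).
#' @export
index_to_world <- function(grid, index) {
  index <- rbind(index)
  sweep(sweep(index - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' Voxel index containing a world point
#'
#' Rounds to the nearest voxel center; points outside the grid return
#' indices outside `1:dims`.
#'
#' @param grid a [voxel_grid()].
#' @param point world position (mm) or n x 3 matrix thereof.
#' @return n x 3 integer matrix of 1-based indices.
#' @export
world_to_index <- function(grid, point) {
  point <- rbind(point)
  idx <- sweep(sweep(point, 2, grid$origin, `-`), 2, grid$spacing, `/`)
  matrix(as.integer(round(idx)) + 1L, ncol = 3)
}

point_in_grid <- function(grid, point) {
  lo <- grid$origin - 0.5 * grid$spacing
  hi <- grid$origin + (grid$dims - 0.5) * grid$spacing
  all(point > lo & point < hi)
}

# Linear (column-major) index of 1-based voxel triples; NA when out of grid.
linear_index <- function(grid, index) {
  index <- rbind(index)
  ok <- index[, 1] >= 1 & index[, 1] <= grid$dims[1] &
        index[, 2] >= 1 & index[, 2] <= grid$dims[2] &
        index[, 3] >= 1 & index[, 3] <= grid$dims[3]
  out <- rep(NA_integer_, nrow(index))
  out[ok] <- index[ok, 1] + grid$dims[1] *
    ((index[ok, 2] - 1L) + grid$dims[2] * (index[ok, 3] - 1L))
  out
}

# Trilinear interpolation of grid values at arbitrary world points (n x 3).
# Points outside the grid interior sample the clamped edge value.
interp_trilinear <- function(grid, points) {
  points <- rbind(points)
  f <- sweep(sweep(points, 2, grid$origin, `-`), 2, grid$spacing, `/`)
  f <- pmin(pmax(f, 0), matrix(rep(grid$dims - 1L, each = nrow(f)), ncol = 3))
  i0 <- pmin(floor(f), matrix(rep(grid$dims - 2L, each = nrow(f)), ncol = 3))
  i0 <- pmax(i0, 0)
  w <- f - i0
  v <- grid$values
  res <- numeric(nrow(points))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    idx <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
    res <- res + wt * v[idx]
  }
  res
}

#' Structure set
#'
#' Named binary masks sharing one grid geometry. `BODY` and `PTV` are
#' required; any other labels (organs at risk) are optional. The PTV must be
#' non-empty and contained in BODY.
#'
#' @param masks named list of logical 3-D arrays, all with the grid's dims.
#' @param grid the reference [voxel_grid()].
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, grid) {
  if (is.null(names(masks)) || any(names(masks) == ""))
    clrt_abort("all masks must be named", "clrt_invalid_argument")
  for (lab in c("BODY", "PTV"))
    if (!lab %in% names(masks))
      clrt_abort(sprintf("required structure '%s' is missing", lab),
                 "clrt_invalid_argument")
  for (lab in names(masks)) {
    m <- masks[[lab]]
    if (!is.array(m) || !identical(dim(m), as.integer(grid$dims)))
      clrt_abort(sprintf("mask '%s' does not match the grid dims", lab),
                 "clrt_invalid_argument")
    storage.mode(masks[[lab]]) <- "logical"
  }
  if (!any(masks$PTV))
    clrt_abort("PTV mask is empty", "clrt_invalid_geometry")
  if (any(masks$PTV & !masks$BODY))
    clrt_abort("PTV extends outside BODY", "clrt_invalid_geometry")
  structure(list(masks = masks, dims = as.integer(grid$dims)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set>\n")
  for (lab in names(x$masks))
    cat(sprintf("  %-12s %d voxels\n", lab, sum(x$masks[[lab]])))
  invisible(x)
}

#' Structure volume in cc
#'
#' @param structures a [structure_set()].
#' @param label structure name.
#' @param grid the reference [voxel_grid()] (for the voxel volume).
#' @export
structure_volume_cc <- function(structures, label, grid) {
  if (!label %in% names(structures$masks))
    clrt_abort(sprintf("unknown structure '%s'", label), "clrt_config_error")
  sum(structures$masks[[label]]) * voxel_volume_cc(grid)
}
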