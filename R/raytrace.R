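#' Radiological (water-equivalent) path length
#'
#' Exact voxel traversal of the segment from `p0` to `p1` through the
#' density grid: the sum over traversed voxels of geometric intersection
#' length times density (g/cc used directly as the water-equivalence
#' factor). The segment is clipped to the grid; the result is symmetric in
#' its endpoints.
#'
#' @param density density [voxel_grid()], g/cc.
#' @param p0,p1 world endpoints, mm.
#' @return Water-equivalent length in mm.
#' @examples
#' g <- voxel_grid(array(1, c(30, 30, 30)), c(2, 2, 2))
#' radiological_path(g, c(0, 29, 29), c(50, 29, 29))  # 50
#' @export
radiological_path <- function(density, p0, p1) {
  stopifnot(inherits(density, "voxel_grid"))
  p0 <- vec3(p0, "p0"); p1 <- vec3(p1, "p1")
  if (sqrt(sum((p1 - p0)^2)) < 1e-9)
    clrt_abort("degenerate segment: endpoints coincide", "clrt_degenerate_segment")
  cpp_radiological_path(as.numeric(density$values), as.integer(density$dims),
                        density$spacing, density$origin, p0, p1)
}

#' Water-equivalent depth of a point along a beam direction
#'
#' Finds the body entry point — the outermost BODY crossing walking from
#' `point` against the beam direction — and returns the radiological path
#' from that entry to `point`. This is the depth the depth-feasibility
#' criterion compares against the lens's `max_depth`.
#'
#' @param density density [voxel_grid()], g/cc.
#' @param body logical BODY mask.
#' @param point world position (mm), inside BODY.
#' @param direction beam axis unit vector (entrance toward the point).
#' @return Water-equivalent depth in mm.
#' @export
depth_to_point <- function(density, body, point, direction) {
  stopifnot(inherits(density, "voxel_grid"))
  point <- vec3(point, "point")
  direction <- normalize3(direction)
  li <- linear_index(density, world_to_index(density, point))
  if (is.na(li) || !body[li])
    clrt_abort("point lies outside BODY", "clrt_invalid_geometry")
  res <- cpp_entry_trace(as.numeric(density$values), as.integer(body),
                         as.integer(density$dims), density$spacing,
                         density$origin, point, -direction)
  if (res[5] < 0.5)
    clrt_abort("no body-surface crossing found along -direction",
               "clrt_no_surface_crossing")
  res[1]
}
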