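#' Deterministic near-uniform directions on the unit sphere
#'
#' Fibonacci spiral lattice; the standard low-discrepancy sampling for
#' candidate beam directions.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Sample focal target points inside the PTV
#'
#' Lays a cubic lattice of pitch `spacing_factor * lateral_fwhm` (slightly
#' wider than the beam's lateral FWHM, so neighbouring focal volumes tile
#' the target without gaps), anchored at the PTV centroid, and keeps the
#' nodes whose containing voxel belongs to the PTV. If no lattice node
#' falls inside the PTV (target smaller than the pitch) the PTV centroid is
#' returned as the single target point.
#'
#' @param ptv logical PTV mask.
#' @param grid the reference [voxel_grid()].
#' @param lateral_fwhm beam lateral FWHM, mm.
#' @param spacing_factor lattice pitch as a multiple (>= 1) of the lateral
#'   FWHM; default 1.2.
#' @return data.frame with columns `id`, `x`, `y`, `z` (mm).
#' @export
sample_target_points <- function(ptv, grid, lateral_fwhm, spacing_factor = 1.2) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!any(ptv)) clrt_abort("PTV mask is empty", "clrt_invalid_geometry")
  if (!is_number(spacing_factor) || spacing_factor < 1)
    clrt_abort("spacing_factor must be >= 1", "clrt_invalid_argument")
  pitch <- spacing_factor * lateral_fwhm
  idx <- which(ptv, arr.ind = TRUE)
  pts <- index_to_world(grid, idx)
  centroid <- colMeans(pts)

  half <- ceiling((apply(pts, 2, function(v) diff(range(v))) / 2) / pitch) + 1
  offs <- lapply(half, function(h) seq(-h, h) * pitch)
  lattice <- as.matrix(expand.grid(x = offs[[1]] + centroid[1],
                                   y = offs[[2]] + centroid[2],
                                   z = offs[[3]] + centroid[3]))
  li <- linear_index(grid, world_to_index(grid, lattice))
  keep <- !is.na(li) & ptv[ifelse(is.na(li), 1L, li)]
  nodes <- lattice[keep, , drop = FALSE]
  if (nrow(nodes) == 0) {
    # centroid fallback, snapped into the PTV if its voxel is not in it
    ci <- linear_index(grid, world_to_index(grid, centroid))
    if (is.na(ci) || !ptv[ci]) {
      d2 <- rowSums(sweep(pts, 2, centroid)^2)
      centroid <- pts[which.min(d2), ]
    }
    nodes <- rbind(centroid)
  }
  ord <- order(nodes[, 3], nodes[, 2], nodes[, 1])
  nodes <- nodes[ord, , drop = FALSE]
  data.frame(id = seq_len(nrow(nodes)), x = nodes[, 1], y = nodes[, 2],
             z = nodes[, 3], row.names = NULL)
}

#' Viable angular approach region of a target point
#'
#' Evaluates a deterministic Fibonacci lattice of candidate beam
#' directions: a candidate is feasible when a body-surface entry exists
#' along it and the water-equivalent depth of the target point does not
#' exceed the lens's `max_depth`.
#'
#' @param point numeric triple (mm) or one row of
#'   [sample_target_points()] output.
#' @param density density [voxel_grid()].
#' @param body logical BODY mask.
#' @param lens a [lens_spec()] (supplies `max_depth`).
#' @param n_candidates number of candidate directions (>= 8); default 256.
#' @return An object of class `approach_region`: list with `point_id`,
#'   `point`, `directions` (n x 3), `feasible` (logical), `depth` (mm,
#'   `NA` where no surface crossing exists).
#' @export
compute_approach_region <- function(point, density, body, lens,
                                    n_candidates = 256) {
  stopifnot(inherits(lens, "lens_spec"))
  if (n_candidates < 8)
    clrt_abort("n_candidates must be at least 8", "clrt_invalid_argument")
  pid <- 1L
  if (is.data.frame(point)) {
    pid <- as.integer(point$id[1])
    point <- c(point$x[1], point$y[1], point$z[1])
  }
  point <- vec3(point, "point")
  li <- linear_index(density, world_to_index(density, point))
  if (is.na(li) || !body[li])
    clrt_abort("point lies outside BODY", "clrt_invalid_geometry")
  dirs <- fibonacci_sphere(n_candidates)
  res <- cpp_depth_batch(as.numeric(density$values), as.integer(body),
                         as.integer(density$dims), density$spacing,
                         density$origin, point, dirs)
  depth <- res[, 1]
  feasible <- !is.na(depth) & depth <= lens$max_depth
  structure(list(point_id = pid, point = point, directions = dirs,
                 feasible = feasible, depth = depth),
            class = "approach_region")
}

#' @export
print.approach_region <- function(x, ...) {
  cat(sprintf("<approach_region> point %d: %d/%d candidate directions feasible\n",
              x$point_id, sum(x$feasible), length(x$feasible)))
  invisible(x)
}

#' Assign diversified beam directions from an approach region
#'
#' Partitions the feasible directions into `n_segments` groups of
#' near-equal size by seeded k-means on the unit vectors (chordal metric)
#' and returns, per non-empty group, the member closest to the group
#' centroid (ties broken by lowest candidate index). When `n_segments`
#' reaches or exceeds the number of feasible candidates, all feasible
#' candidates are returned.
#'
#' @param region an [compute_approach_region()] result.
#' @param n_segments number of angular segments (>= 1); default 5.
#' @param seed integer seed for the clustering.
#' @return m x 3 matrix of unit direction vectors (m <= n_segments).
#' @export
assign_directions <- function(region, n_segments = 5, seed = 1L) {
  stopifnot(inherits(region, "approach_region"))
  if (n_segments < 1)
    clrt_abort("n_segments must be >= 1", "clrt_invalid_argument")
  feas_idx <- which(region$feasible)
  if (length(feas_idx) == 0)
    clrt_abort(sprintf("target point %d is unreachable: no feasible direction",
                       region$point_id), "clrt_unreachable_target")
  F <- region$directions[feas_idx, , drop = FALSE]
  m <- nrow(F)
  if (n_segments >= m) return(F)
  cl <- withr::with_seed(as.integer(seed),
    kmeans(F, centers = n_segments, nstart = 10, iter.max = 100))
  picked <- integer(0)
  for (gid in sort(unique(cl$cluster))) {
    members <- which(cl$cluster == gid)
    d2 <- rowSums(sweep(F[members, , drop = FALSE], 2,
                        cl$centers[gid, ])^2)
    best <- members[which(d2 <= min(d2) + 1e-12)]
    picked <- c(picked, min(best))  # lowest candidate index on ties
  }
  picked <- sort(unique(picked))
  F[picked, , drop = FALSE]
}
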