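# Shared fixtures, built in code at test time.

# Homogeneous water grid with an all-body mask; origin at 0.
water_grid <- function(dims, spacing) {
  list(grid = voxel_grid(array(1.0, dims), spacing),
       body = array(TRUE, dims))
}

# Water slab: body (and unit density) for z in [z0, z1] (world mm), air
# elsewhere; grid origin at 0 so voxel boundaries sit at odd multiples of
# spacing/2.
slab_phantom <- function(dims, spacing, z0, z1, density = 1.0) {
  zc <- (seq_len(dims[3]) - 1) * spacing[3]
  inside <- zc > z0 & zc < z1
  vals <- array(0, dims)
  vals[, , inside] <- density
  body <- array(FALSE, dims)
  body[, , inside] <- TRUE
  list(grid = voxel_grid(vals, spacing), body = body)
}

# Small random heterogeneous density grid (water-ish with hot/cold spots).
random_density_grid <- function(dims, spacing, seed) {
  withr::with_seed(seed, {
    vals <- array(runif(prod(dims), 0.2, 1.9), dims)
  })
  voxel_grid(vals, spacing)
}

# Dense-sampling oracle for the radiological path: nearest-voxel lookup at
# a fixed fine step (independent of the exact interval-walking code path).
dense_path_oracle <- function(grid, p0, p1, step = 0.01) {
  L <- sqrt(sum((p1 - p0)^2))
  n <- max(2, ceiling(L / step))
  ts <- (seq_len(n) - 0.5) / n
  pts <- outer(rep(1, n), p0) + outer(ts, p1 - p0)
  idx <- world_to_index(grid, pts)
  li <- clrt:::linear_index(grid, idx)
  dens <- ifelse(is.na(li), 0, grid$values[ifelse(is.na(li), 1L, li)])
  sum(dens) * L / n
}

# Hand-built dose-influence object from a dense matrix (voxels laid out
# along the first grid axis); for optimizer unit tests.
toy_dij <- function(Ddense, spacing = c(2, 2, 2)) {
  nvox <- nrow(Ddense)
  beams <- lapply(seq_len(ncol(Ddense)), function(j)
    beam(c(0, 0, 0), c(0, 0, 1)))
  structure(list(
    D = Matrix::Matrix(Ddense, sparse = TRUE),
    beams = beams,
    grid = list(dims = c(nvox, 1L, 1L), spacing = spacing,
                origin = c(0, 0, 0))
  ), class = "dose_influence")
}

# Structure set over the toy 1-D voxel layout.
toy_structures <- function(nvox, ptv_idx, extra = list()) {
  body <- array(TRUE, c(nvox, 1, 1))
  ptv <- array(FALSE, c(nvox, 1, 1))
  ptv[ptv_idx, 1, 1] <- TRUE
  masks <- c(list(BODY = body, PTV = ptv), extra)
  grid <- voxel_grid(array(0, c(nvox, 1, 1)), c(2, 2, 2))
  structure_set(masks, grid)
}

# Parametric spherical dose field: full prescription inside r100, linear
# falloff reaching 50% at r50 and 0 at r50 + (r50 - r100).
spherical_falloff_dose <- function(dims, spacing, prescription, r100, r50) {
  ctr <- (dims - 1) * spacing / 2
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a] - ctr[a])
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
  vals <- array(prescription * pmax(0, pmin(1, 1 - 0.5 * (r - r100) / (r50 - r100))),
                dims)
  list(dose = voxel_grid(vals, spacing),
       ptv = r <= r100, center = ctr, r = r)
}

# Case-1-like water phantom (small deep-seated spherical metastasis).
case1_phantom <- function(dims = c(60, 60, 60), spacing = c(2, 2, 2),
                          ptv_radius = 4.41, seed = 1L) {
  make_phantom("water_box", dims = dims, spacing = spacing,
               ptv_radius = ptv_radius, seed = seed)
}
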