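test_that("built-in lenses carry the published focal sizes", {
  a <- builtin_lens("A")
  expect_equal(a$fwhm_longitudinal, 22.5)
  expect_equal(a$fwhm_lateral, 3.4)
  expect_equal(a$energy, 60)
  b <- builtin_lens("B")
  expect_equal(b$fwhm_longitudinal, 10.8)
  expect_equal(b$fwhm_lateral, 1.3)
  expect_error(builtin_lens("C"), class = "clrt_unknown_lens")
})

test_that("lens spec validates its geometry", {
  expect_error(lens_spec(3.4, 22.5, cone_inner_half_angle = 30,
                         cone_outer_half_angle = 25), class = "clrt_error")
  expect_error(lens_spec(3.4, 22.5, peak_to_entrance_ratio = 0.5),
               class = "clrt_error")
  expect_error(lens_spec(-1, 22.5), class = "clrt_error")
})

test_that("profile FWHM measurement matches known profiles", {
  # exact Gaussian, FWHM 10 mm, sampled on a 0.2 mm line
  n <- 301
  x <- (seq_len(n) - 1) * 0.2 - 30
  sig <- 10 / (2 * sqrt(2 * log(2)))
  vals <- array(rep(exp(-x^2 / (2 * sig^2)), 9), c(n, 3, 3))
  g <- voxel_grid(vals, c(0.2, 5, 5))
  ctr <- c(30, 5, 5)
  expect_equal(measure_profile_fwhm(g, ctr, c(1, 0, 0), 0.2), 10,
               tolerance = 0.2 / 10)
  # triangle peaking at the center, reaching zero at +/- 5 mm: FWHM 5
  tri <- array(rep(pmax(0, 1 - abs(x) / 5), 9), c(n, 3, 3))
  gt <- voxel_grid(tri, c(0.2, 5, 5))
  expect_equal(measure_profile_fwhm(gt, ctr, c(1, 0, 0), 0.2), 5,
               tolerance = 1e-6)
  # unresolved profile errors out
  flat <- voxel_grid(array(1, c(n, 3, 3)), c(0.2, 5, 5))
  expect_error(measure_profile_fwhm(flat, ctr, c(1, 0, 0), 0.2),
               class = "clrt_profile_unresolved")
})

test_that("focal dose is normalized to 1 per unit weight at the focus", {
  wg <- water_grid(c(41, 41, 41), c(1, 1, 1))
  ctr <- c(20, 20, 20)
  d <- beam_dose(builtin_lens("B"), beam(ctr, c(0, 0, 1)), wg$grid, wg$body)
  expect_equal(d$values[21, 21, 21], 1.0, tolerance = 1e-12)
  expect_error(beam_dose(builtin_lens("B"), beam(c(-50, 0, 0), c(0, 0, 1)),
                         wg$grid, wg$body),
               class = "clrt_invalid_geometry")
})

test_that("cone-shell dose follows the attenuated convergence law", {
  lens <- builtin_lens("A")
  sp <- 1
  dims <- c(101, 101, 101)
  sl <- slab_phantom(dims, rep(sp, 3), z0 = 3, z1 = 98)
  focus <- c(50, 50, 80)  # voxel center, deep in the slab
  d <- beam_dose(lens, beam(focus, c(0, 0, 1)), sl$grid, sl$body)

  # voxel centers exactly on one cone ray: steps of (0, -3, -8) mm from the
  # focus give a polar angle atan(3/8) = 20.6 deg, inside the 20-25 deg shell
  ks <- 3:7
  vox <- t(vapply(ks, function(k) focus + k * c(0, -3, -8), numeric(3)))
  doses <- d$values[world_to_index(d, vox)]
  expect_true(all(doses > 0))

  # analytic expectation: entry at the z = 3.5 body face along the ray
  step_len <- sqrt(3^2 + 8^2)
  r <- ks * step_len                         # distance voxel -> focus
  z_face <- 3.5                              # lower boundary of first body voxel
  r_entry <- (focus[3] - z_face) / (8 / step_len)
  depth <- r_entry - r                       # water-equivalent (unit density)
  geom <- r_entry / pmax(r, lens$fwhm_longitudinal)
  expected <- (1 / lens$peak_to_entrance_ratio) * geom *
    exp(-lens$mu_water * depth)
  expect_equal(doses, expected, tolerance = 1e-9)

  # log-dose with the geometric factor removed is linear in depth with
  # slope -mu_water
  y <- log(doses / geom)
  fit <- lm(y ~ depth)
  expect_equal(unname(coef(fit)[2]), -lens$mu_water, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-6)

  # pairwise ratios follow exp(-mu * delta-depth) once geometry is removed
  ratio <- (doses[2] / geom[2]) / (doses[1] / geom[1])
  expect_equal(ratio, exp(-lens$mu_water * (depth[2] - depth[1])),
               tolerance = 1e-9)
})

test_that("beam dose is non-negative, zero outside the body, with no cone downstream", {
  wg <- slab_phantom(c(40, 40, 40), c(2, 2, 2), z0 = 6, z1 = 72)
  lens <- builtin_lens("B")
  withr::with_seed(5, {
    for (rep in 1:5) {
      tgt <- c(runif(2, 25, 55), runif(1, 25, 55))
      dir <- clrt:::normalize3(rnorm(3))
      ti <- clrt:::linear_index(wg$grid, world_to_index(wg$grid, tgt))
      if (is.na(ti) || !wg$body[ti]) next
      d <- beam_dose(lens, beam(tgt, dir), wg$grid, wg$body)
      expect_true(all(d$values >= 0))
      expect_true(all(d$values[!wg$body] == 0))
      # downstream of the focus, beyond the focal Gaussian: exactly zero
      idx <- which(d$values > 0, arr.ind = TRUE)
      w <- index_to_world(d, idx)
      rel <- sweep(w, 2, tgt)
      lz <- as.numeric(rel %*% dir)
      expect_true(all(lz[d$values[idx] > 0] <= 5 * clrt:::fwhm_to_sigma(lens$fwhm_longitudinal) + 1e-9))
    }
  })
})

test_that("the dose kernel recovers both lens FWHMs in water at fine resolution", {
  for (nm in c("A", "B")) {
    lens <- builtin_lens(nm)
    sp <- 0.25
    half_long <- ceiling(1.4 * lens$fwhm_longitudinal / sp)
    half_lat <- ceiling(3 * lens$fwhm_lateral / sp) + 8
    dims <- c(2 * half_lat + 1, 2 * half_lat + 1, 2 * half_long + 1)
    wg <- water_grid(dims, rep(sp, 3))
    ctr <- (dims - 1) * sp / 2
    d <- beam_dose(lens, beam(ctr, c(0, 0, 1)), wg$grid, wg$body)
    expect_equal(measure_profile_fwhm(d, ctr, c(1, 0, 0), sp / 2),
                 lens$fwhm_lateral, tolerance = (sp / 2) / lens$fwhm_lateral)
    expect_equal(measure_profile_fwhm(d, ctr, c(0, 0, 1), sp / 2),
                 lens$fwhm_longitudinal,
                 tolerance = (sp / 2) / lens$fwhm_longitudinal)
  }
})
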