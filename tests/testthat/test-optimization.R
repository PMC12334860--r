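test_that("dose influence columns superpose and match single-beam kernels", {
  wg <- slab_phantom(c(30, 30, 30), c(2, 2, 2), z0 = 4, z1 = 54)
  lens <- builtin_lens("B")
  ctr <- c(29, 29, 29)
  beams <- list(beam(ctr, c(0, 0, 1)),
                beam(ctr, c(0, 0, 1)),
                beam(ctr + c(3, 0, 0), c(0, 1, 0)))
  dij <- assemble_dij(beams, lens, wg$grid, wg$body)
  expect_equal(dim(dij$D), c(prod(wg$grid$dims), 3L))
  expect_true(all(dij$D@x >= 0))
  # identical beams give identical columns
  expect_equal(dij$D[, 1], dij$D[, 2])
  # column 1 equals the (thresholded) standalone kernel
  d1 <- as.numeric(beam_dose(lens, beams[[1]], wg$grid, wg$body)$values)
  d1[d1 < 1e-6 * max(d1)] <- 0
  expect_equal(as.numeric(dij$D[, 1]), d1, tolerance = 1e-12)
  # superposition: D %*% 1 is the sum of the column fields
  acc <- accumulate_dose(dij, c(1, 1, 1))
  expect_lt(max(abs(acc$values -
                      array(as.numeric(dij$D[, 1] + dij$D[, 2] + dij$D[, 3]),
                            wg$grid$dims))), 1e-9)
})

test_that("the one-sided quadratic objective evaluates per its definition", {
  D <- matrix(1, 1, 1)
  dij <- toy_dij(D)
  st <- toy_structures(1, 1)
  under <- list(objective("PTV", "squared_underdose", 10, 1))
  over <- list(objective("PTV", "squared_overdose", 10, 1))
  # exactly at prescription: zero from either side (Heaviside(0) = 0)
  expect_equal(objective_value(10, dij, under, st), 0)
  expect_equal(objective_value(10, dij, over, st), 0)
  # 8 Gy on a 10 Gy prescription: underdose (10-8)^2 = 4, overdose 0
  expect_equal(objective_value(8, dij, under, st), 4)
  expect_equal(objective_value(8, dij, over, st), 0)
  # penalties scale linearly; unknown structures are config errors
  expect_equal(objective_value(8, dij,
                               list(objective("PTV", "squared_underdose", 10, 2.5)), st), 10)
  expect_error(objective_value(8, dij,
                               list(objective("CORD", "squared_underdose", 10, 1)), st),
               class = "clrt_config_error")
})

test_that("the analytic gradient matches hand differentiation and finite differences", {
  # single beam, single voxel, D11 = 1, w = 8, dhat = 10: gradient 2(8-10) = -4
  dij <- toy_dij(matrix(1, 1, 1))
  st <- toy_structures(1, 1)
  under <- list(objective("PTV", "squared_underdose", 10, 1))
  expect_equal(objective_gradient(8, dij, under, st), -4)
  # zero gradient at exact prescription everywhere
  expect_equal(objective_gradient(10, dij, under, st), 0)

  # finite-difference agreement on random instances
  withr::with_seed(2024, {
    for (rep in 1:100) {
      nv <- 60; nb <- 5
      D <- matrix(runif(nv * nb) * (runif(nv * nb) < 0.4), nv, nb)
      dij <- toy_dij(D)
      st <- toy_structures(nv, sample(nv, 20),
                           extra = list(OAR = array(c(rep(FALSE, 40),
                                                      rep(TRUE, 20)), c(nv, 1, 1))))
      objs <- list(objective("PTV", "squared_underdose", 10, runif(1, 0.5, 5)),
                   objective("PTV", "squared_overdose", 10, runif(1, 0.5, 5)),
                   objective("OAR", "squared_overdose", 4, runif(1, 0.5, 5)))
      w <- runif(nb, 0.5, 8)
      # keep clear of the Heaviside kink so the derivative exists
      d <- as.numeric(dij$D %*% w)
      if (min(abs(c(d - 10, d - 4))) < 1e-3) next
      g <- objective_gradient(w, dij, objs, st)
      h <- 1e-6
      fd <- vapply(seq_len(nb), function(j) {
        e <- numeric(nb); e[j] <- h
        (objective_value(w + e, dij, objs, st) -
           objective_value(w - e, dij, objs, st)) / (2 * h)
      }, 0)
      expect_lt(max(abs(g - fd)) / max(max(abs(fd)), 1e-8), 1e-5)
    }
  })
})

test_that("the optimizer recovers the closed-form single-beam solution", {
  dij <- toy_dij(matrix(2, 1, 1))
  st <- toy_structures(1, 1)
  objs <- list(objective("PTV", "squared_underdose", 10, 1),
               objective("PTV", "squared_overdose", 10, 1))
  plan <- optimize_weights(dij, objs, list(), st,
                           opts = list(max_iter = 200, tol = 1e-12))
  expect_equal(plan$weights, 5, tolerance = 1e-6)  # w* = dhat / D11
  expect_lt(plan$trace[length(plan$trace)], 1e-10)
  # degenerate twin columns: same objective value as the closed form
  dij2 <- toy_dij(matrix(2, 1, 2))
  plan2 <- optimize_weights(dij2, objs, list(), st,
                            opts = list(max_iter = 200, tol = 1e-12))
  expect_equal(sum(plan2$weights), 5, tolerance = 1e-6)
  expect_lt(objective_value(plan2$weights, dij2, objs, st), 1e-10)
  # zero-iteration budget returns the scaled initial weights, trace length 1
  plan0 <- optimize_weights(dij, objs, list(), st, opts = list(max_iter = 0))
  expect_length(plan0$trace, 1L)
  expect_equal(plan0$weights, 5)  # initial scaling already solves this one
  # a problem with no active penalty is rejected
  expect_error(optimize_weights(dij, list(objective("PTV", "squared_underdose", 10, 0)),
                                list(), st),
               class = "clrt_degenerate_problem")
})

test_that("objective traces decrease monotonically on random problems", {
  withr::with_seed(77, {
    for (rep in 1:8) {
      nv <- 80; nb <- 12
      D <- matrix(runif(nv * nb) * (runif(nv * nb) < 0.3), nv, nb)
      dij <- toy_dij(D)
      st <- toy_structures(nv, sample(nv, 25))
      objs <- list(objective("PTV", "squared_underdose", 10, 100),
                   objective("PTV", "squared_overdose", 10, 50),
                   objective("BODY", "squared_overdose", 10, 1))
      plan <- optimize_weights(dij, objs, list(), st,
                               opts = list(max_iter = 120, tol = 1e-10))
      expect_true(all(diff(plan$trace) <= 1e-12))
      expect_true(all(plan$weights >= 0))
      expect_identical(plan$dose$values,
                       accumulate_dose(dij, plan$weights)$values)
    }
  })
})

test_that("mean and max dose constraints are honoured via penalties", {
  nv <- 40
  D <- cbind(c(rep(1, 20), rep(0.8, 20)), c(rep(0.2, 20), rep(1.2, 20)))
  dij <- toy_dij(D)
  st <- toy_structures(nv, 1:20,
                       extra = list(OAR = array(c(rep(FALSE, 20), rep(TRUE, 20)),
                                                c(nv, 1, 1))))
  objs <- list(objective("PTV", "squared_underdose", 10, 100),
               objective("PTV", "squared_overdose", 10, 100))
  cons <- list(constraint("OAR", "max_dose", upper_gy = 5))
  plan <- optimize_weights(dij, objs, cons, st,
                           opts = list(max_iter = 400, tol = 1e-12))
  oar_dose <- as.numeric(dij$D[21:40, ] %*% plan$weights)
  expect_lt(max(oar_dose), 5 + 0.2)  # small penalty-method slack
  expect_equal(max(plan$constraint_violation), max(0, max(oar_dose) - 5),
               tolerance = 1e-9)
})

test_that("dose accumulation is the exact matrix-vector product", {
  dij <- toy_dij(matrix(c(1, 3, 2, 4), 2, 2))  # [[1,2],[3,4]]
  expect_equal(as.numeric(accumulate_dose(dij, c(1, 2))$values), c(5, 11))
  expect_equal(as.numeric(accumulate_dose(dij, c(0, 0))$values), c(0, 0))
  expect_equal(as.numeric(accumulate_dose(dij, c(1, 0))$values), c(1, 3))
  expect_error(accumulate_dose(dij, c(1, 2, 3)),
               class = "clrt_dimension_mismatch")
  # scaling covariance: c*D with w/c leaves the dose invariant
  dij10 <- toy_dij(10 * matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(accumulate_dose(dij10, c(1, 2) / 10)$values,
               accumulate_dose(dij, c(1, 2))$values)
})
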