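#' Dose objective specification
#'
#' One one-sided quadratic dose objective on a structure: the mean, over
#' the structure's voxels, of the squared deviation from the prescribed
#' dose counted only on the under- (or over-) dosed side, gated by the
#' Heaviside function with the convention `H(0) = 0` (a voxel exactly at
#' the prescription contributes nothing from either side).
#'
#' @param structure structure label (e.g. `"PTV"`).
#' @param kind `"squared_underdose"` or `"squared_overdose"`.
#' @param dose_gy prescribed dose d-hat, Gy (> 0).
#' @param penalty non-negative weight of this objective in the total sum.
#' @return An object of class `clrt_objective`.
#' @export
objective <- function(structure, kind = c("squared_underdose", "squared_overdose"),
                      dose_gy, penalty = 1) {
  kind <- match.arg(kind)
  if (!is_number(dose_gy) || dose_gy <= 0)
    clrt_abort("dose_gy must be > 0", "clrt_invalid_argument")
  if (!is_number(penalty) || penalty < 0)
    clrt_abort("penalty must be >= 0", "clrt_invalid_argument")
  structure(list(structure = structure, kind = kind, dose_gy = dose_gy,
                 penalty = penalty), class = "clrt_objective")
}

#' Dose constraint specification
#'
#' A bound on the per-voxel maximum dose or on the mean dose of a
#' structure, enforced during optimization by a fixed quadratic penalty
#' (violations are reported on the resulting plan).
#'
#' @param structure structure label.
#' @param kind `"max_dose"` or `"mean_dose"`.
#' @param lower_gy,upper_gy bounds in Gy (`-Inf`/`Inf` for one-sided).
#' @return An object of class `clrt_constraint`.
#' @export
constraint <- function(structure, kind = c("max_dose", "mean_dose"),
                       lower_gy = -Inf, upper_gy = Inf) {
  kind <- match.arg(kind)
  if (lower_gy > upper_gy)
    clrt_abort("constraint lower bound exceeds upper bound",
               "clrt_invalid_argument")
  structure(list(structure = structure, kind = kind, lower_gy = lower_gy,
                 upper_gy = upper_gy), class = "clrt_constraint")
}

#' Assemble the dose-influence matrix
#'
#' Column j holds the per-unit-weight dose field of beam j (see
#' [beam_dose()]), flattened over the grid; entries below `1e-6` of the
#' column maximum are dropped for sparsity. The final dose of a weighted
#' plan is the matrix-vector product `D %*% w`.
#'
#' @param beams list of [beam()]s.
#' @param lens a [lens_spec()].
#' @param density density [voxel_grid()].
#' @param body logical BODY mask.
#' @param sparsity_floor relative column threshold below which entries are
#'   zeroed; default `1e-6`.
#' @return An object of class `dose_influence`: list with the sparse
#'   matrix `D` (voxels x beams), `beams`, and the grid geometry.
#' @export
assemble_dij <- function(beams, lens, density, body, sparsity_floor = 1e-6) {
  if (length(beams) < 1)
    clrt_abort("need at least one beam", "clrt_invalid_argument")
  nvox <- prod(density$dims)
  ivec <- vector("list", length(beams))
  xvec <- vector("list", length(beams))
  for (j in seq_along(beams)) {
    d <- beam_dose(lens, beams[[j]], density, body)$values
    d <- as.numeric(d)
    thr <- sparsity_floor * max(d)
    nz <- which(d >= thr & d > 0)
    ivec[[j]] <- nz
    xvec[[j]] <- d[nz]
  }
  counts <- lengths(ivec)
  D <- Matrix::sparseMatrix(
    i = unlist(ivec), j = rep(seq_along(beams), counts),
    x = unlist(xvec), dims = c(nvox, length(beams))
  )
  structure(list(D = D, beams = beams,
                 grid = list(dims = as.integer(density$dims),
                             spacing = density$spacing,
                             origin = density$origin)),
            class = "dose_influence")
}

#' @export
print.dose_influence <- function(x, ...) {
  cat(sprintf("<dose_influence> %d voxels x %d beams, %d nonzeros\n",
              nrow(x$D), ncol(x$D), Matrix::nnzero(x$D)))
  invisible(x)
}

structure_rows <- function(dij, structures, label) {
  if (!label %in% names(structures$masks))
    clrt_abort(sprintf("unknown structure '%s' in objectives/constraints", label),
               "clrt_config_error")
  which(structures$masks[[label]])
}

one_sided_term <- function(d, dhat, kind) {
  dev <- if (kind == "squared_underdose") pmin(d - dhat, 0) else pmax(d - dhat, 0)
  dev[d == dhat] <- 0  # Heaviside(0) = 0 on both sides
  dev
}

#' Weighted-sum objective of a beam-weight vector
#'
#' `f(w) = sum_n p_n f_n(w)` where each `f_n` is the structure-mean squared
#' one-sided deviation of `d = D w` from the prescribed dose.
#'
#' @param w non-negative beam weights, one per dose-influence column.
#' @param dij an [assemble_dij()] result.
#' @param objectives list of [objective()]s.
#' @param structures a [structure_set()] on the dose-influence grid.
#' @return Non-negative scalar objective value.
#' @export
objective_value <- function(w, dij, objectives, structures) {
  if (length(w) != ncol(dij$D))
    clrt_abort("length(w) must equal the number of beams", "clrt_invalid_argument")
  total <- 0
  for (ob in objectives) {
    rows <- structure_rows(dij, structures, ob$structure)
    d <- as.numeric(dij$D[rows, , drop = FALSE] %*% w)
    dev <- one_sided_term(d, ob$dose_gy, ob$kind)
    total <- total + ob$penalty * mean(dev^2)
  }
  total
}

#' Analytic gradient of the weighted-sum objective
#'
#' @inheritParams objective_value
#' @return Gradient vector over beams; matches central finite differences
#'   of [objective_value()].
#' @export
objective_gradient <- function(w, dij, objectives, structures) {
  if (length(w) != ncol(dij$D))
    clrt_abort("length(w) must equal the number of beams", "clrt_invalid_argument")
  g <- numeric(ncol(dij$D))
  for (ob in objectives) {
    rows <- structure_rows(dij, structures, ob$structure)
    DS <- dij$D[rows, , drop = FALSE]
    d <- as.numeric(DS %*% w)
    dev <- one_sided_term(d, ob$dose_gy, ob$kind)
    g <- g + ob$penalty * (2 / length(rows)) *
      as.numeric(Matrix::crossprod(DS, dev))
  }
  g
}

# Penalized objective/gradient including constraint penalty terms.
penalized_fg <- function(dij, objectives, constraints, structures, mu) {
  ob_pre <- lapply(objectives, function(ob) {
    rows <- structure_rows(dij, structures, ob$structure)
    list(DS = dij$D[rows, , drop = FALSE], n = length(rows),
         dhat = ob$dose_gy, p = ob$penalty, kind = ob$kind)
  })
  ct_pre <- lapply(constraints, function(ct) {
    rows <- structure_rows(dij, structures, ct$structure)
    list(DS = dij$D[rows, , drop = FALSE], n = length(rows),
         lo = ct$lower_gy, hi = ct$upper_gy, kind = ct$kind)
  })
  fn <- function(w) {
    total <- 0
    for (p in ob_pre) {
      dev <- one_sided_term(as.numeric(p$DS %*% w), p$dhat, p$kind)
      total <- total + p$p * mean(dev^2)
    }
    for (p in ct_pre) {
      d <- as.numeric(p$DS %*% w)
      if (p$kind == "max_dose") {
        v <- pmax(d - p$hi, 0) + pmax(p$lo - d, 0)
        total <- total + mu * mean(v^2)
      } else {
        md <- mean(d)
        total <- total + mu * (max(md - p$hi, 0)^2 + max(p$lo - md, 0)^2)
      }
    }
    total
  }
  gr <- function(w) {
    g <- numeric(ncol(dij$D))
    for (p in ob_pre) {
      dev <- one_sided_term(as.numeric(p$DS %*% w), p$dhat, p$kind)
      g <- g + p$p * (2 / p$n) * as.numeric(Matrix::crossprod(p$DS, dev))
    }
    for (p in ct_pre) {
      d <- as.numeric(p$DS %*% w)
      if (p$kind == "max_dose") {
        v <- pmax(d - p$hi, 0) - pmax(p$lo - d, 0)
        g <- g + mu * (2 / p$n) * as.numeric(Matrix::crossprod(p$DS, v))
      } else {
        md <- mean(d)
        s <- max(md - p$hi, 0) - max(p$lo - md, 0)
        if (s != 0)
          g <- g + mu * 2 * s * as.numeric(Matrix::crossprod(p$DS, rep(1 / p$n, p$n)))
      }
    }
    g
  }
  list(fn = fn, gr = gr, ct_pre = ct_pre)
}

#' Optimize non-negative beam weights
#'
#' Minimizes the weighted-sum one-sided quadratic objective over `w >= 0`
#' by a monotone spectral projected-gradient method: Barzilai-Borwein step
#' length, Armijo backtracking, projection onto the non-negative orthant.
#' Constraints enter as fixed quadratic penalty terms (multiplier
#' `constraint_mu`); residual violations are reported on the plan. Initial
#' weights are uniform, scaled so the mean PTV dose equals the PTV
#' objective's prescription. The accepted-objective trace is non-increasing
#' after the first entry by construction.
#'
#' @param dij an [assemble_dij()] result.
#' @param objectives list of [objective()]s; at least one must have a
#'   positive penalty.
#' @param constraints list of [constraint()]s (may be empty).
#' @param structures a [structure_set()] on the dose-influence grid.
#' @param opts list with `max_iter` (default 500), `tol` (relative
#'   objective change, default 1e-6), `constraint_mu` (default 1e4),
#'   `seed` (unused by the deterministic optimizer, accepted for interface
#'   symmetry).
#' @param prescription plan prescription in Gy; defaults to the PTV
#'   objective's dose.
#' @param fractions number of fractions recorded on the plan; default 1.
#' @return An object of class `clrt_plan`: beams with optimized weights,
#'   the accumulated final dose grid, the objective trace, prescription,
#'   fractions, and a constraint-violation report.
#' @export
optimize_weights <- function(dij, objectives, constraints = list(),
                             structures, opts = list(),
                             prescription = NULL, fractions = 1L) {
  opts <- modifyList(list(max_iter = 500L, tol = 1e-6, constraint_mu = 1e4,
                          seed = 1L), opts)
  if (length(objectives) == 0 || all(vapply(objectives, `[[`, 0, "penalty") == 0))
    clrt_abort("degenerate problem: all objective penalties are zero",
               "clrt_degenerate_problem")
  ptv_obj <- Filter(function(o) o$structure == "PTV", objectives)
  if (is.null(prescription))
    prescription <- if (length(ptv_obj)) ptv_obj[[1]]$dose_gy else
      objectives[[1]]$dose_gy

  B <- ncol(dij$D)
  ptv_rows <- structure_rows(dij, structures, "PTV")
  mean_unit <- mean(as.numeric(dij$D[ptv_rows, , drop = FALSE] %*% rep(1, B)))
  w <- rep(if (mean_unit > 0) prescription / mean_unit else 0, B)

  fg <- penalized_fg(dij, objectives, constraints, structures,
                     opts$constraint_mu)
  f <- fg$fn(w)
  trace <- f
  alpha <- 1
  it <- 0L
  converged <- FALSE
  g <- fg$gr(w)
  while (it < opts$max_iter) {
    it <- it + 1L
    f_new <- f; w_new <- w
    step <- alpha
    accepted <- FALSE
    for (bt in 1:60) {
      w_try <- pmax(w - step * g, 0)
      if (all(w_try == w)) break
      f_try <- fg$fn(w_try)
      if (f_try <= f - 1e-4 * sum(g * (w - w_try))) {
        w_new <- w_try; f_new <- f_try; accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    g_new <- fg$gr(w_new)
    s <- w_new - w
    y <- g_new - g
    sy <- sum(s * y)
    alpha <- if (sy > 1e-30) min(max(sum(s * s) / sy, 1e-10), 1e10) else step
    rel <- (f - f_new) / max(abs(f), 1e-30)
    w <- w_new; f <- f_new; g <- g_new
    trace <- c(trace, f)
    if (rel < opts$tol) { converged <- TRUE; break }
  }

  dose <- accumulate_dose(dij, w)
  viol <- lapply(fg$ct_pre, function(p) {
    d <- as.numeric(p$DS %*% w)
    if (p$kind == "max_dose")
      max(c(0, d - p$hi, p$lo - d))
    else
      max(0, mean(d) - p$hi, p$lo - mean(d))
  })
  beams <- dij$beams
  for (j in seq_along(beams)) beams[[j]]$weight <- w[j]
  structure(
    list(beams = beams, weights = w, dose = dose, trace = trace,
         prescription = prescription, fractions = as.integer(fractions),
         iterations = it, converged = converged,
         constraint_violation = if (length(viol)) unlist(viol) else numeric(0)),
    class = "clrt_plan"
  )
}

#' @export
print.clrt_plan <- function(x, ...) {
  cat(sprintf("<clrt_plan> %d beams, prescription %g Gy in %d fraction(s)\n",
              length(x$weights), x$prescription, x$fractions))
  cat(sprintf("  objective %g -> %g in %d iterations (%s)\n",
              x$trace[1], x$trace[length(x$trace)], x$iterations,
              if (x$converged) "converged" else "budget exhausted"))
  if (length(x$constraint_violation))
    cat(sprintf("  max constraint violation %g Gy\n",
                max(x$constraint_violation)))
  invisible(x)
}

#' Accumulate the weighted dose distribution
#'
#' The final dose of a plan: the exact matrix-vector product of the
#' dose-influence matrix with the weight vector, mapped back onto the
#' grid. Linear in `w`.
#'
#' @param dij an [assemble_dij()] result.
#' @param w beam weights, one per column.
#' @return A dose [voxel_grid()] in Gy.
#' @export
accumulate_dose <- function(dij, w) {
  if (length(w) != ncol(dij$D))
    clrt_abort("length(w) must equal the number of beams",
               "clrt_dimension_mismatch")
  d <- as.numeric(dij$D %*% w)
  voxel_grid(array(d, dij$grid$dims), dij$grid$spacing, dij$grid$origin)
}
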