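#' Run the full planning pipeline
#'
#' Executes the planning workflow end to end: sample focal target points
#' in the PTV, compute each point's depth-feasible approach region, assign
#' a diversified direction set per point, assemble the dose-influence
#' matrix, optimize the beam weights, accumulate the final dose, and
#' evaluate DVHs and plan indices. Fully deterministic for a fixed config
#' seed. Stage timings and beam counts are logged to stderr.
#'
#' @param config a [planning_config()] (or plain list passed through it).
#' @param density density [voxel_grid()], g/cc.
#' @param structures a [structure_set()]; must contain every structure
#'   referenced by objectives and constraints (validated before any
#'   computation).
#' @param out_dir optional output directory; when given, writes
#'   `dose.nrrd`, `plan.txt`, `dvh.csv`, `indices.txt`.
#' @param verbose log per-point feasible-depth statistics.
#' @return List with `plan` (a `clrt_plan`), `indices`
#'   ([plan_indices()]), `dvhs` (list of [compute_dvh()] curves per
#'   structure), and `target_points`.
#' @export
run_pipeline <- function(config, density, structures, out_dir = NULL,
                         verbose = FALSE) {
  if (!inherits(config, "planning_config")) config <- planning_config(config)
  stopifnot(inherits(density, "voxel_grid"), inherits(structures, "structure_set"))
  refs <- unique(c(
    vapply(config$objectives, function(o) o$structure, ""),
    vapply(config$constraints, function(ct) ct$structure, character(1))
  ))
  missing <- setdiff(refs, names(structures$masks))
  if (length(missing))
    clrt_abort(sprintf("config references unknown structure(s): %s",
                       paste(missing, collapse = ", ")), "clrt_config_error")

  lens <- config_lens(config)
  body <- structures$masks$BODY
  ptv <- structures$masks$PTV
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      clrt_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 "clrt_stage_error")
    })
    message(sprintf("[clrt] %-18s %.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  points <- stage("target sampling", sample_target_points(
    ptv, density, lens$fwhm_lateral, config$sampling$spacing_factor))
  message(sprintf("[clrt] %d target point(s)", nrow(points)))

  beams <- stage("angle assignment", {
    out <- list()
    for (i in seq_len(nrow(points))) {
      region <- compute_approach_region(points[i, ], density, body, lens,
                                        config$sampling$n_candidates)
      if (!any(region$feasible)) {
        message(sprintf("[clrt] target point %d unreachable (min depth %.1f mm); skipped",
                        points$id[i], suppressWarnings(min(region$depth, na.rm = TRUE))))
        next
      }
      if (verbose)
        message(sprintf("[clrt]   point %d: %d feasible, depth %.1f-%.1f mm",
                        points$id[i], sum(region$feasible),
                        min(region$depth[region$feasible]),
                        max(region$depth[region$feasible])))
      dirs <- assign_directions(region, config$sampling$n_segments,
                                config$sampling$seed)
      pt <- c(points$x[i], points$y[i], points$z[i])
      for (r in seq_len(nrow(dirs)))
        out[[length(out) + 1]] <- beam(pt, dirs[r, ])
    }
    out
  })
  if (length(beams) == 0)
    clrt_abort("stage 'angle assignment' failed: no deliverable beam for any target point",
               "clrt_stage_error")
  message(sprintf("[clrt] %d beam(s)", length(beams)))

  dij <- stage("dose influence", assemble_dij(beams, lens, density, body))
  plan <- stage("weight optimization", optimize_weights(
    dij, config_objectives(config), config_constraints(config), structures,
    opts = config$optimizer, prescription = config$prescription_gy,
    fractions = config$fractions))
  message(sprintf("[clrt] objective %.4g -> %.4g (%d iterations)",
                  plan$trace[1], plan$trace[length(plan$trace)],
                  plan$iterations))

  evald <- stage("evaluation", {
    idx <- plan_indices(plan$dose, ptv, config$prescription_gy)
    bw <- config$prescription_gy / 1000  # 0.1% of prescription
    dvhs <- lapply(names(structures$masks), function(lab)
      compute_dvh(plan$dose, structures$masks[[lab]], bw, structure = lab))
    names(dvhs) <- names(structures$masks)
    list(indices = idx, dvhs = dvhs)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_nrrd(plan$dose, file.path(out_dir, "dose.nrrd"))
    write_plan(plan, file.path(out_dir, "plan.txt"))
    write_dvh_csv(evald$dvhs, file.path(out_dir, "dvh.csv"))
    write_indices_report(evald$indices, file.path(out_dir, "indices.txt"))
  }
  list(plan = plan, indices = evald$indices, dvhs = evald$dvhs,
       target_points = points)
}
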