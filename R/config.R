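default_planning_config <- function() {
  list(
    version = 1L,
    lens = "B",
    prescription_gy = 27,
    fractions = 1L,
    sampling = list(spacing_factor = 1.2, n_candidates = 256L,
                    n_segments = 5L, seed = 1L, max_depth_mm = 80),
    objectives = list(
      list(structure = "PTV", kind = "squared_underdose", dose_gy = 27,
           penalty = 1000),
      list(structure = "PTV", kind = "squared_overdose", dose_gy = 27,
           penalty = 500),
      list(structure = "BODY", kind = "squared_overdose", dose_gy = 27,
           penalty = 10)
    ),
    constraints = list(),
    optimizer = list(max_iter = 500L, tol = 1e-6, constraint_mu = 1e4)
  )
}

#' Build and validate a planning configuration
#'
#' Merges user settings over the package defaults and fail-fast validates:
#' unknown keys (at the top level and inside `sampling` / `optimizer`) are
#' rejected, the prescription must be positive, fractions at least 1, and
#' the objective list must target the PTV (all PTV objectives at the
#' prescription dose). `lens` is either a built-in name (`"A"`/`"B"`) or a
#' named list of [lens_spec()] arguments.
#'
#' @param config named list of settings (e.g. from [read_planning_config()]).
#' @return The validated, fully populated config (class `planning_config`).
#' @export
planning_config <- function(config = list()) {
  base <- default_planning_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    clrt_abort(sprintf("unknown config key(s): %s",
                       paste(unknown, collapse = ", ")), "clrt_config_error")
  # objectives/constraints are replaced, not merged element-wise
  for (k in c("objectives", "constraints"))
    if (!is.null(config[[k]])) base[[k]] <- config[[k]]
  cfg <- modifyList(base, config[setdiff(names(config),
                                         c("objectives", "constraints"))])
  for (blk in c("sampling", "optimizer")) {
    bad <- setdiff(names(cfg[[blk]]), names(default_planning_config()[[blk]]))
    if (length(bad))
      clrt_abort(sprintf("unknown %s key(s): %s", blk,
                         paste(bad, collapse = ", ")), "clrt_config_error")
  }
  if (!is_number(cfg$prescription_gy) || cfg$prescription_gy <= 0)
    clrt_abort("prescription_gy must be > 0", "clrt_config_error")
  if (!is_number(cfg$fractions) || cfg$fractions < 1)
    clrt_abort("fractions must be >= 1", "clrt_config_error")
  ptv_obj <- Filter(function(o) identical(o$structure, "PTV"), cfg$objectives)
  if (length(ptv_obj) == 0)
    clrt_abort("at least one objective must target the PTV", "clrt_config_error")
  for (o in ptv_obj)
    if (!isTRUE(all.equal(o$dose_gy, cfg$prescription_gy)))
      clrt_abort("PTV objective dose must equal prescription_gy",
                 "clrt_config_error")
  structure(cfg, class = c("planning_config", "list"))
}

#' Read a planning configuration from YAML
#'
#' @param path YAML file.
#' @return A validated [planning_config()].
#' @export
read_planning_config <- function(path) {
  planning_config(yaml::read_yaml(path))
}

config_lens <- function(cfg) {
  lens <- if (is.character(cfg$lens)) builtin_lens(cfg$lens) else
    do.call(lens_spec, cfg$lens)
  md <- cfg$sampling$max_depth_mm
  if (!is.null(md)) lens$max_depth <- md
  lens
}

config_objectives <- function(cfg) {
  lapply(cfg$objectives, function(o)
    objective(o$structure, o$kind, o$dose_gy, o$penalty %||% 1))
}

config_constraints <- function(cfg) {
  lapply(cfg$constraints, function(ct)
    constraint(ct$structure, ct$kind, ct$lower_gy %||% -Inf,
               ct$upper_gy %||% Inf))
}
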