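#' Pipeline configuration
#'
#' All knobs of the end-to-end build in one validated list. Unknown keys are
#' rejected so config typos cannot silently fall back to defaults. Values
#' can come from a YAML file (`config_file`) and be overridden by arguments.
#'
#' @param input path to an `.swc` or `.asc` tracing.
#' @param output path of the exported mesh (`.obj`, `.off` or `.ply`).
#' @param cross_sections,points_per_section tube resolution, see
#'   [resolution_params()].
#' @param subdivisions,reduction_fraction,stiffness,internal_stiffness,damping,mass,dt,max_steps,kinetic_tolerance,pull_distance_scale,roi_threshold_scale
#'   soma deformation settings, see [deform_params()].
#' @param smooth smoothing iterations (0 disables).
#' @param smooth_factor Laplacian factor in (0, 1).
#' @param min_radius clamp for zero radii, micrometres.
#' @param spines logical: distribute spines.
#' @param spine_profile optional path to a density profile file.
#' @param seed integer seed for spine sampling.
#' @param allow_open if `TRUE`, a non-closed result is exported with a
#'   warning instead of failing.
#' @param verbose log stage timings.
#' @param config_file optional YAML file of the same keys.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, output = NULL,
                            cross_sections = 4L, points_per_section = 6L,
                            subdivisions = 3L, reduction_fraction = 0.5,
                            stiffness = 10, internal_stiffness = 1,
                            damping = 0.5, mass = 1, dt = 0.01,
                            max_steps = 20000L, kinetic_tolerance = 1e-8,
                            pull_distance_scale = 1, roi_threshold_scale = 1,
                            smooth = 2L, smooth_factor = 0.3,
                            min_radius = 0.05,
                            spines = FALSE, spine_profile = NULL, seed = 1L,
                            allow_open = FALSE, verbose = TRUE,
                            config_file = NULL) {
  defaults <- as.list(environment())
  defaults$config_file <- NULL
  if (!is.null(config_file)) {
    file_vals <- yaml::read_yaml(config_file)
    unknown <- setdiff(names(file_vals), names(defaults))
    if (length(unknown))
      nm_arg_error(sprintf("unknown config key(s): %s",
                           paste(unknown, collapse = ", ")))
    supplied <- names(as.list(match.call()))[-1]
    for (k in setdiff(names(file_vals), supplied)) defaults[[k]] <- file_vals[[k]]
  }
  structure(defaults, class = "pipeline_config")
}

#' Run the full neuron meshing pipeline
#'
#' parse -> soma -> neurites -> assembly -> (spines) -> smoothing ->
#' validation -> export. A non-closed result is a hard failure unless
#' `allow_open` is set. The returned report and log make every fallback and
#' clamp visible.
#'
#' @param config a [pipeline_config()] with at least `input` set (or a
#'   [neuron_morphology()] passed via `morphology`).
#' @param morphology optional pre-parsed [neuron_morphology()] overriding
#'   `config$input`.
#' @return invisibly, a list: `mesh`, `report` ([validate_mesh()] result),
#'   `log` (character vector of stage messages), `output` (path or NULL).
#' @export
run_pipeline <- function(config = pipeline_config(), morphology = NULL) {
  log <- character(0)
  t0 <- proc.time()[["elapsed"]]
  note <- function(fmt, ...) {
    line <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t0,
                    sprintf(fmt, ...))
    log <<- c(log, line)
    if (isTRUE(config$verbose)) nm_log(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      nm_stop(sprintf("stage '%s' failed: %s (hint: see ?run_pipeline)",
                      name, conditionMessage(e)), "nm_pipeline_error")
    })
  }
  m <- if (!is.null(morphology)) morphology else stage("parse", {
    if (is.null(config$input) || !file.exists(config$input))
      nm_arg_error(sprintf("input file not found: %s",
                           config$input %||% "<missing>"))
    if (grepl("\\.asc$", config$input, ignore.case = TRUE))
      parse_asc(config$input) else parse_swc(config$input)
  })
  note("parsed morphology: %d points, %d stems", nrow(m$points),
       length(m$stems))
  params <- deform_params(
    stiffness = config$stiffness, internal_stiffness = config$internal_stiffness,
    damping = config$damping, mass = config$mass, dt = config$dt,
    max_steps = config$max_steps, kinetic_tolerance = config$kinetic_tolerance,
    subdivisions = config$subdivisions,
    reduction_fraction = config$reduction_fraction,
    pull_distance_scale = config$pull_distance_scale,
    roi_threshold_scale = config$roi_threshold_scale)
  res <- resolution_params(config$cross_sections, config$points_per_section)
  mesh <- stage("assemble", assemble_neuron(
    m, res = res, params = params, smooth_iterations = 0L,
    min_radius = config$min_radius))
  note("assembled neuron: %d triangles", n_faces(mesh))
  if (isTRUE(config$spines)) {
    profile <- if (!is.null(config$spine_profile))
      read_density_profile(config$spine_profile) else spine_density_profile()
    pl <- stage("spines", sample_spine_positions(m, profile, seed = config$seed))
    mesh <- stage("spines", place_spines(mesh, pl, seed = config$seed))
    note("placed %d spines", nrow(pl))
  }
  if (config$smooth > 0L) {
    mesh <- stage("smooth", laplacian_smooth(
      mesh, iterations = config$smooth, factor = config$smooth_factor,
      protected = attr(mesh, "junction_vertices") %||% integer(0)))
    note("smoothed: %d iterations, factor %.2f", config$smooth,
         config$smooth_factor)
  }
  report <- stage("validate", validate_mesh(mesh))
  note("validated: closed=%s, chi=%d, volume=%.4g um^3", report$closed,
       report$euler_characteristic, report$volume %||% NA)
  if (!report$closed && !isTRUE(config$allow_open))
    nm_stop(sprintf(
      "assembled mesh is not closed (%d boundary, %d non-manifold edges); use allow_open to export anyway",
      report$boundary_edges, report$nonmanifold_edges), "nm_pipeline_error")
  out <- NULL
  if (!is.null(config$output)) {
    out <- stage("export", export_mesh(mesh, config$output))
    note("exported %s", out)
  }
  invisible(list(mesh = mesh, report = report, log = log, output = out))
}
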