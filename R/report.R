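# Run configuration and end-to-end pipeline orchestration:
# synthesize -> mesh -> slice -> solve -> sample -> post-process -> classify,
# with CSV/JSON outputs.

#' Build a pipeline run configuration
#'
#' One configuration object drives the whole pipeline; every model default
#' (fluid properties, friction law, classifier thresholds) is surfaced here
#' so analyses can pin them. Either a template/spec (synthetic geometry) or
#' a mesh path plus dividing-plane landmark must be given.
#'
#' @param template synthetic template name passed to [airway_spec()], or
#'   `NULL` when `mesh_path` is used.
#' @param mesh_path path to an STL surface mesh (mm), or `NULL`.
#' @param spec an [airway_spec()] overriding `template`.
#' @param dividing_index plane index of the soft-palate tip; required for
#'   external meshes (for synthetic specs it defaults to the spec landmark).
#' @param top_z,bottom_z axial slicing range, mm; defaults to the mesh z
#'   range for synthetic geometry.
#' @param spacing_mm plane spacing, mm.
#' @param Q_lpm inspiratory flow rate, L/min.
#' @param fluid a [fluid_properties()].
#' @param solver a [solver_config()].
#' @param theta_exp,theta_rec classifier thresholds ([classify_levels()]).
#' @param recirc_strength,jet_core_fraction field-generator parameters
#'   ([make_flow_field()]).
#' @param seed integer seed for all stochastic stages.
#' @return List of class `run_config`.
#' @export
run_config <- function(template = NULL, mesh_path = NULL, spec = NULL,
                       dividing_index = NULL,
                       top_z = NULL, bottom_z = NULL, spacing_mm = 0.5,
                       Q_lpm = 18,
                       fluid = fluid_properties(),
                       solver = solver_config(),
                       theta_exp = 1.5, theta_rec = 0.10,
                       recirc_strength = 0.2, jet_core_fraction = NULL,
                       seed = 1L) {
  if (is.null(spec) && is.null(template) && is.null(mesh_path)) {
    stop("one of 'spec', 'template' or 'mesh_path' is required",
         call. = FALSE)
  }
  if (!is.null(template) && is.null(spec)) {
    spec <- airway_spec(template, spacing_mm = spacing_mm, seed = seed)
  }
  if (is.null(spec) && is.null(dividing_index)) {
    stop("missing required field 'dividing_index': the soft-palate-tip ",
         "landmark cannot be inferred from a bare mesh", call. = FALSE)
  }
  structure(
    list(spec = spec, mesh_path = mesh_path,
         dividing_index = dividing_index,
         top_z = top_z, bottom_z = bottom_z, spacing_mm = spacing_mm,
         Q_lpm = Q_lpm, fluid = fluid, solver = solver,
         theta_exp = theta_exp, theta_rec = theta_rec,
         recirc_strength = recirc_strength,
         jet_core_fraction = jet_core_fraction,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `template`, `mesh_path`, `dividing_index`, `top_z`,
#' `bottom_z`, `spacing_mm`, `Q_lpm`, `theta_exp`, `theta_rec`,
#' `recirc_strength`, `seed`, plus nested `fluid: {rho, mu}` and
#' `solver: {friction_model, expansion_loss, contraction_loss_coeff}`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  fluid <- do.call(fluid_properties, as.list(y$fluid))
  solver_args <- as.list(y$solver)
  solver_args$Q_lpm <- y$Q_lpm %||% 18
  solver <- do.call(solver_config, solver_args)
  run_config(template = y$template, mesh_path = y$mesh_path,
             dividing_index = y$dividing_index,
             top_z = y$top_z, bottom_z = y$bottom_z,
             spacing_mm = y$spacing_mm %||% 0.5,
             Q_lpm = y$Q_lpm %||% 18,
             fluid = fluid, solver = solver,
             theta_exp = y$theta_exp %||% 1.5,
             theta_rec = y$theta_rec %||% 0.10,
             recirc_strength = y$recirc_strength %||% 0.2,
             seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pressure-loss pipeline and write its report files
#'
#' Chains geometry synthesis (or mesh loading), plane slicing, region
#' assignment, the quasi-1D solve, flow-field sampling, post-processing and
#' level classification, then writes `morphometry.json`, `planes.csv`,
#' `subsegments.csv` and `levels.json` into `out_dir`. Deterministic under
#' a fixed config seed; any stage failure is re-signalled with the stage
#' name prepended.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if missing), or `NULL` to skip
#'   writing.
#' @return List with `sections`, `morphometry`, `solution`, `field`,
#'   `postproc`, `levels`, and `files` (paths written).
#' @export
run_report <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  synth <- !is.null(cfg$spec)
  if (synth) {
    profile <- stage("synth-airway", make_area_profile(cfg$spec))
    mesh <- stage("synth-airway", make_surface_mesh(profile, cfg$spec))
    top_z <- cfg$top_z %||% max(profile$z_mm)
    bottom_z <- cfg$bottom_z %||% min(profile$z_mm)
    dividing <- cfg$dividing_index %||% profile$landmarks$dividing
  } else {
    mesh <- stage("read-mesh", read_stl(cfg$mesh_path))
    top_z <- cfg$top_z %||% max(mesh$vertices[, 3L])
    bottom_z <- cfg$bottom_z %||% min(mesh$vertices[, 3L])
    dividing <- cfg$dividing_index
  }

  sections <- stage("slice",
                    slice_airway(mesh, top_z, bottom_z, cfg$spacing_mm))
  sections <- stage("slice", assign_regions(sections, dividing))
  morpho <- stage("morphometry", morphometry_report(sections))

  # the solve runs on the sliced areas, so external meshes follow the same
  # path as synthetic ones
  sliced_profile <- structure(
    list(z_mm = sections$z_mm, area_mm2 = sections$area_mm2,
         spacing_mm = cfg$spacing_mm,
         landmarks = list(top = 1L, dividing = dividing,
                          bottom = nrow(sections),
                          amin = find_plane_amin(sections))),
    class = "area_profile"
  )
  solution <- stage("solve1d",
                    solve_quasi1d(sliced_profile, cfg$fluid, cfg$solver))
  field <- stage("synth-flow",
                 make_flow_field(sliced_profile, Q_lpm = cfg$Q_lpm,
                                 jet_core_fraction = cfg$jet_core_fraction,
                                 recirc_strength = cfg$recirc_strength,
                                 fluid = cfg$fluid, cfg = cfg$solver,
                                 seed = cfg$seed))
  post <- stage("postproc", postprocess_field(field, sections))
  rf <- stage("classify", reverse_flow_fractions(field))
  amin <- sliced_profile$landmarks$amin
  levels <- stage("classify",
                  classify_levels(sections, amin, rf,
                                  cfg$theta_exp, cfg$theta_rec))
  post$subsegments$level <- levels$labels[-length(levels$labels)]

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      morphometry = file.path(out_dir, "morphometry.json"),
      planes = file.path(out_dir, "planes.csv"),
      subsegments = file.path(out_dir, "subsegments.csv"),
      levels = file.path(out_dir, "levels.json")
    )
    jsonlite::write_json(unclass(morpho), files[["morphometry"]],
                         auto_unbox = TRUE, digits = NA)
    write_plane_table(post, sections, files[["planes"]])
    write_subsegment_table(post, files[["subsegments"]])
    jsonlite::write_json(
      list(level2_start = levels$level2_start,
           level3_start = levels$level3_start,
           labels = levels$labels,
           reverse_fractions = levels$reverse_fractions,
           theta_exp = levels$theta_exp, theta_rec = levels$theta_rec),
      files[["levels"]], auto_unbox = TRUE, digits = NA)
  }
  list(sections = sections, morphometry = morpho, solution = solution,
       field = field, postproc = post, levels = levels, files = files)
}

#' Write the per-plane result table
#'
#' Columns: `plane_index`, `z_mm`, `area_mm2`, `region`, `area_ratio_next`,
#' `ps_pa`, `v_ms`, `tke_m2s2`, `pv_pa`, `pt_pa`, `pt_prime_pa`.
#'
#' @param post an [postprocess_field()] result.
#' @param sections the matching `plane_sections`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plane_table <- function(post, sections, path) {
  p <- post$planes
  out <- data.frame(
    plane_index = p$index, z_mm = p$z_mm, area_mm2 = p$area_mm2,
    region = sections$region[match(p$index, sections$index)],
    area_ratio_next = c(area_ratio_series(sections), NA),
    ps_pa = p$ps_pa, v_ms = p$v_ms, tke_m2s2 = p$tke_m2s2,
    pv_pa = p$pv_pa, pt_pa = p$pt_pa, pt_prime_pa = p$pt_prime_pa
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the per-subsegment result table
#'
#' Columns: `subseg_index`, `dpt_pa`, `K`, `R_pa_s2_m6`, `wss_mean_pa`,
#' `wall_area_mm2`, `frictional_pa`, `interior_pa`, `level`.
#'
#' @param post an [postprocess_field()] result (with `level` attached by
#'   [run_report()], otherwise NA).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_subsegment_table <- function(post, path) {
  s <- post$subsegments
  out <- data.frame(
    subseg_index = s$index, dpt_pa = s$dpt_pa, K = s$K,
    R_pa_s2_m6 = s$R_pa_s2_m6, wss_mean_pa = s$wss_mean_pa,
    wall_area_mm2 = s$wall_area_mm2,
    frictional_pa = s$frictional_pa, interior_pa = s$interior_pa,
    level = if ("level" %in% names(s)) s$level else NA_integer_
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write flow-field samples to CSV
#'
#' Plane samples: `plane_index`, `z_mm`, `x_mm`, `y_mm`, `area_weight_mm2`,
#' `ux_ms`, `uy_ms`, `uz_ms`, `ps_pa`, `tke_m2s2`. Wall samples:
#' `subseg_index`, `patch_area_mm2`, `wss_pa`.
#'
#' @param field a `flow_field_samples` object.
#' @param planes_path,walls_path output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_field_csv <- function(field, planes_path, walls_path) {
  utils::write.csv(field$planes, planes_path, row.names = FALSE)
  utils::write.csv(field$walls, walls_path, row.names = FALSE)
  invisible(c(planes_path, walls_path))
}

#' Read flow-field samples from CSV
#'
#' Inverse of [write_field_csv()].
#'
#' @param planes_path,walls_path CSV paths.
#' @param flow_direction unit bulk flow direction.
#' @param rho gas density, kg/m^3.
#' @param Q_lpm volumetric flow rate, L/min.
#' @return A `flow_field_samples` object.
#' @export
read_field_csv <- function(planes_path, walls_path,
                           flow_direction = c(0, 0, -1),
                           rho = 1.204, Q_lpm = 18) {
  structure(
    list(planes = utils::read.csv(planes_path),
         walls = utils::read.csv(walls_path),
         flow_direction = flow_direction, rho = rho, Q_lpm = Q_lpm),
    class = "flow_field_samples"
  )
}
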