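#' Pipeline configuration
#'
#' Central configuration for the end-to-end run: stage toggles, the
#' synthetic-volume spec, ROI sampling settings (830 um squares extended
#' 500 um deep, subpleural threshold 830 um, 500-attempt cap), model
#' preparation settings (x3 upsampling, cubic median window 3), the fluid
#' parameter set, and solver options.  Defaults reproduce the study's
#' stated settings.
#'
#' @param synthetic a [synthetic_spec()].
#' @param sampling list: `n_rois`, `roi_side_um`, `depth_um`,
#'   `threshold_um`, `max_iter`, `z_plane`, `seed`.
#' @param prep list: `upsample`, `median_window`, `shrinkage_scale`, and
#'   optionally `distal_faces` (explicit three distal face names,
#'   overriding the pleural-distance rule).
#' @param fluid a [fluid_parameters()].
#' @param solver list: `tol`, `max_backflow_iters`, `method`.
#' @param report list: `sensitivity_factors`, `sensitivity_targets`,
#'   `sensitivity_refine` (run the grid-refinement error estimate).
#' @param stages character subset of
#'   `c("synth", "morpho", "prep", "flow", "sens", "stats")`.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_spec(),
                            sampling = list(n_rois = 25L, roi_side_um = 830,
                                            depth_um = 500,
                                            threshold_um = 830,
                                            max_iter = 500L, z_plane = NULL,
                                            seed = NULL),
                            prep = list(upsample = 3L, median_window = 3L,
                                        shrinkage_scale = 1),
                            fluid = fluid_parameters(),
                            solver = list(tol = 1e-10,
                                          max_backflow_iters = 20L,
                                          method = "auto"),
                            report = list(sensitivity_factors = c(100, 0.01),
                                          sensitivity_targets = c("K_L",
                                                                  "K_B",
                                                                  "u_L"),
                                          sensitivity_refine = TRUE),
                            stages = c("synth", "morpho", "prep", "flow",
                                       "sens", "stats"),
                            seed = 1L) {
  structure(list(synthetic = synthetic, sampling = sampling, prep = prep,
                 fluid = fluid, solver = solver, report = report,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' Round-trips losslessly through YAML.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return [write_pipeline_config()]: `path` invisibly;
#'   [read_pipeline_config()]: a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path, precision = 17L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sp <- y$synthetic
  spec <- synthetic_spec(
    shape = unlist(sp$shape), voxel_pitch_um = sp$voxel_pitch_um,
    target_lymph_vf_at_pleura = sp$target_lymph_vf_at_pleura,
    lymph_vf_gradient = sp$lymph_vf_gradient,
    blood_tree = sp$blood_tree,
    lymph_network = lapply(sp$lymph_network, unlist),
    openings = lapply(sp$openings, function(v) unlist(v)),
    air_fraction = sp$air_fraction, pleural_slab = sp$pleural_slab,
    pleural_face = if (is.null(sp$pleural_face)) "z-" else sp$pleural_face,
    depth_bin_um = sp$depth_bin_um, seed = sp$seed)
  fl <- do.call(fluid_parameters, y$fluid)
  rp <- y$report
  rp$sensitivity_factors <- unlist(rp$sensitivity_factors)
  rp$sensitivity_targets <- unlist(rp$sensitivity_targets)
  pipeline_config(synthetic = spec, sampling = y$sampling, prep = y$prep,
                  fluid = fl, solver = y$solver, report = rp,
                  stages = unlist(y$stages), seed = y$seed)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(unclass(config), function(v) v,
                              how = "replace"),
                       tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order -- synthetic volume generation,
#' ROI sampling + morphometry, model preparation, flow solve, parameter
#' sensitivity, distance statistics -- writing CSV/JSON artifacts (each
#' stamped with the configuration hash and seed) into `out_dir`.  A stage
#' failure halts the run with a stage-named error; artifacts of completed
#' stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("pulmolymph run %s\nconfig %s seed %d\n",
              format(Sys.time()), hash, config$seed),
      file = log_path)
  res <- list(config_hash = hash)
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(invisible(NULL))
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logf("stage %s: ok", name)
    out
  }
  meta <- list(config_hash = hash, seed = config$seed)

  res$synth <- stage("synth", {
    sp <- config$synthetic
    sp$seed <- derive_seed(config$seed, 1L)
    g <- generate_voi(sp)
    write_volume(g$volume, file.path(out_dir, "volume.nrrd"))
    write.csv(g$truth$bins, file.path(out_dir, "truth_bins.csv"),
              row.names = FALSE)
    write.csv(g$truth$openings, file.path(out_dir, "truth_openings.csv"),
              row.names = FALSE)
    g
  })

  res$morpho <- stage("morpho", {
    vol <- res$synth$volume
    dm <- pleural_distance_map(vol)
    zp <- config$sampling$z_plane
    if (is.null(zp)) zp <- max(3L, dim(vol$labels)[1] %/% 2L)
    sd_ <- config$sampling$seed
    if (is.null(sd_)) sd_ <- derive_seed(config$seed, 2L)
    rois <- sample_rois(vol, z_plane = zp,
                        roi_side_um = config$sampling$roi_side_um,
                        n_target = config$sampling$n_rois,
                        max_iter = config$sampling$max_iter, seed = sd_)
    vois <- classify_rois(rois, vol, dm,
                          threshold_um = config$sampling$threshold_um,
                          depth_um = config$sampling$depth_um)
    recs <- measure_vois(vol, vois)
    write.csv(recs, file.path(out_dir, "morphometry.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      c(meta, list(n_rois = nrow(rois),
                   shortfall = attr(rois, "shortfall"))),
      file.path(out_dir, "morphometry_summary.json"),
      auto_unbox = TRUE, digits = NA)
    list(rois = rois, vois = vois, records = recs)
  })

  res$prep <- stage("prep", {
    vol <- res$synth$volume
    model <- prepare_model_volume(
      vol, voi = NULL, upsample = config$prep$upsample,
      median_window = config$prep$median_window,
      shrinkage_scale = config$prep$shrinkage_scale)
    bnd <- identify_vessel_openings(
      model, distal_faces = config$prep$distal_faces)
    jsonlite::write_json(
      c(meta, list(distal_faces = bnd$distal_faces,
                   patches = bnd$patches,
                   removed_component_voxels =
                     as.list(model$provenance$removed_component_voxels))),
      file.path(out_dir, "boundaries.json"), auto_unbox = TRUE, digits = NA)
    list(model = model, boundaries = bnd)
  })

  res$flow <- stage("flow", {
    sol <- solve_flow(
      assemble_flow_system(res$prep$model, res$prep$boundaries,
                           config$fluid),
      tol = config$solver$tol,
      max_backflow_iters = config$solver$max_backflow_iters,
      method = config$solver$method)
    fx <- domain_fluxes(sol)
    jsonlite::write_json(
      c(meta, list(Q_L_in = sol$Q_L_in, Q_B_out = sol$Q_B_out,
                   residual = sol$residuals$total_relative,
                   suppressed_outlet_faces = sol$suppressed_outlet_faces,
                   balance = fx$balance)),
      file.path(out_dir, "flux_report.json"), auto_unbox = TRUE,
      digits = NA)
    export_fields(sol, file.path(out_dir, "fields.vtk"))
    logf("flow residual %.3e, suppressed %d",
         sol$residuals$total_relative, sol$suppressed_outlet_faces)
    sol
  })

  res$sens <- stage("sens", {
    rep <- run_sensitivity(res$prep$model, res$prep$boundaries,
                           config$fluid,
                           factors = config$report$sensitivity_factors,
                           targets = config$report$sensitivity_targets,
                           refine = isTRUE(config$report$sensitivity_refine),
                           tol = config$solver$tol,
                           method = config$solver$method)
    write.csv(cbind(rep$runs, config_hash = hash),
              file.path(out_dir, "sensitivity.csv"), row.names = FALSE)
    rep
  })

  res$stats <- stage("stats", {
    recs <- res$morpho$records
    reg <- correlate_with_distance(recs$median_pleural_distance_um,
                                   recs$volume_fraction,
                                   measure = "volume_fraction")
    if (sum(!recs$excluded_fractal) >= 3)
      reg <- rbind(reg, correlate_with_distance(
        recs$median_pleural_distance_um, recs$fractal_dimension,
        excluded = recs$excluded_fractal, measure = "fractal_dimension"))
    write.csv(cbind(reg, config_hash = hash),
              file.path(out_dir, "distance_regression.csv"),
              row.names = FALSE)
    reg
  })
  invisible(res)
}
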