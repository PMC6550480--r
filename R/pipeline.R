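## allowed keys per config block; unknown keys are rejected before any compute
CONFIG_SCHEMA <- list(
  geometry = c("pore_diameter", "lattice_spacing", "coverage",
               "film_thickness", "reservoir_depth", "n_pores_x", "n_pores_y"),
  solver = c("voxel_size", "tol", "separation", "c_left", "c_right"),
  occlusion = c("mode", "cap_fraction", "disk_radius", "patch_side",
                "occlusion_thickness", "placement_seed"),
  sweep = c("fractions", "mode"),
  infer = c("measured_ratio", "measured"),
  synth = c("true_capping", "flux_scale", "noise_sd_rel", "n_replicates",
            "rejection_midpoint_nm", "rejection_steepness",
            "rejection_noise_sd"),
  characterize = c("rejection_csv", "threshold"),
  output = c("vtk"))

#' Read and validate a pipeline run configuration
#'
#' Parses a YAML configuration describing the geometry, solver settings and
#' requested stages.  Every block is validated against its schema — unknown
#' keys are rejected, and the geometry block is instantiated (so invariant
#' violations surface) before any compute starts.
#'
#' @param path Path to a YAML file, or a pre-parsed list.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) {
    abort("config must be a YAML mapping", class = "aqpore_config")
  }
  known_top <- c("stages", "seed", "log_level", names(CONFIG_SCHEMA))
  extra <- setdiff(names(cfg), known_top)
  if (length(extra)) {
    abort(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")),
          class = "aqpore_config")
  }
  for (blk in intersect(names(cfg), names(CONFIG_SCHEMA))) {
    bad <- setdiff(names(cfg[[blk]]), CONFIG_SCHEMA[[blk]])
    if (length(bad)) {
      abort(sprintf("unknown key(s) in `%s` block: %s", blk,
                    paste(bad, collapse = ", ")), class = "aqpore_config")
    }
  }
  cfg$stages <- cfg$stages %||% c("simulate")
  allowed <- c("synth", "simulate", "sweep", "infer", "characterize")
  if (!all(cfg$stages %in% allowed)) {
    abort(sprintf("unknown stage(s): %s",
                  paste(setdiff(cfg$stages, allowed), collapse = ", ")),
          class = "aqpore_config")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  ## instantiate the geometry now so validation precedes any solve
  cfg$geometry_obj <- do.call(film_geometry, cfg$geometry %||% list())
  if (!is.null(cfg$occlusion)) {
    cfg$occlusion_obj <- do.call(occlusion_spec, cfg$occlusion)
  }
  structure(cfg, class = "run_config")
}

#' Run the analysis pipeline described by a configuration
#'
#' Executes the requested stages in the canonical order
#' `synth -> simulate -> sweep -> infer -> characterize`, writing CSV tables
#' (10 significant digits), an optional VTK field export, a JSON run
#' manifest (config digest, package version, seed) and a plain-text log to
#' the output directory.  Identical config and seed give byte-identical
#' numeric outputs.
#'
#' @param config A [read_run_config()] result, a path to a YAML config, or
#'   a config list.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional seed overriding the config seed.
#' @return Invisibly, the manifest list (with `$files`, the written paths).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_table_csv(df, p)
    files <<- c(files, p)
    logf("wrote %s (%d rows)", name, nrow(df))
  }
  stage <- function(name, code) {
    logf("stage %s: start", name)
    tryCatch(code, error = function(e) {
      logf("stage %s: FAILED (%s); outputs so far are partial", name,
           conditionMessage(e))
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            class = "aqpore_stage")
    })
  }

  geom <- config$geometry_obj
  solver <- config$solver %||% list()
  vx <- solver$voxel_size
  tol <- solver$tol %||% 1e-10
  bc <- boundary_conditions(solver$c_left %||% 1, solver$c_right %||% 0)
  sep <- solver$separation %||% "film"
  dataset <- NULL
  curve <- NULL

  ordered <- intersect(c("synth", "simulate", "sweep", "infer", "characterize"),
                       config$stages)
  for (st in ordered) {
    if (st == "synth") {
      stage("synth", {
        sy <- config$synth %||% list()
        spec <- synthetic_study_spec(
          true_capping = sy$true_capping %||% 0.64,
          geometry = geom,
          flux_scale = sy$flux_scale %||% 60,
          noise_sd_rel = sy$noise_sd_rel %||% 0.05,
          n_replicates = sy$n_replicates %||% 10L,
          seed = config$seed,
          rejection_midpoint_nm = sy$rejection_midpoint_nm %||% 0.60,
          rejection_steepness = sy$rejection_steepness %||% 0.05,
          rejection_noise_sd = sy$rejection_noise_sd %||% 2.5)
        dataset <- generate_flux_measurements(spec)
        dataset$rejection <- generate_rejection_profile(spec)
        emit(dataset$flux, "flux_measurements.csv")
        emit(dataset$rejection, "rejection_profile.csv")
        emit(dataset$truth, "ground_truth.csv")
      })
    } else if (st == "simulate") {
      stage("simulate", {
        dom <- voxelize(geom, config$occlusion_obj, vx)
        field <- solve_steady_state(dom, bc, tol)
        de <- effective_diffusivity(field, sep)
        logf("simulate: residual %.3e, De/D = %.6g", field$residual, de$ratio)
        emit(tidy(de), "effective_diffusivity.csv")
        if (isTRUE((config$output %||% list())$vtk)) {
          p <- file.path(out_dir, "concentration.vtk")
          write_vtk(field, p)
          files <<- c(files, p)
          logf("wrote concentration.vtk")
        }
      })
    } else if (st == "sweep") {
      stage("sweep", {
        sw <- config$sweep %||% list()
        fr <- as.numeric(sw$fractions %||% c(seq(0, 1, by = 0.1), 0.64))
        curve <- sweep_capping(geom, fractions = fr,
                                mode = sw$mode %||% "pore_cap",
                                seed = config$seed, voxel_size = vx,
                                bc = bc, tol = tol)
        emit(as.data.frame(curve), "packing_curve.csv")
      })
    } else if (st == "infer") {
      stage("infer", {
        inf <- config$infer %||% list()
        if (is.null(curve)) {
          abort("infer stage needs a sweep stage before it")
        }
        mr <- inf$measured_ratio %||%
          (if (!is.null(dataset)) flux_ratio(dataset) else
             abort("infer stage needs `measured_ratio` or a synth stage"))
        est <- estimate_packing(curve, mr,
                                measured = inf$measured %||% "flux_ratio")
        emit(tidy(est), "packing_estimate.csv")
      })
    } else if (st == "characterize") {
      stage("characterize", {
        ch <- config$characterize %||% list()
        recs <- if (!is.null(ch$rejection_csv)) {
          utils::read.csv(ch$rejection_csv, fileEncoding = "UTF-8")
        } else if (!is.null(dataset$rejection)) {
          dataset$rejection
        } else {
          abort("characterize stage needs `rejection_csv` or a synth stage")
        }
        mw <- determine_mwco(recs, threshold = ch$threshold %||% 90)
        emit(glance(mw), "mwco.csv")
        emit(tidy(mw), "rejection_table.csv")
      })
    }
  }

  manifest <- list(
    package = "aqpore",
    version = as.character(utils::packageVersion("aqpore")),
    seed = config$seed,
    stages = ordered,
    config_digest = digest::digest(unclass(config)),
    files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("pipeline complete (%d files)", length(files))
  invisible(manifest)
}
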