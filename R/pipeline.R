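# End-to-end run configuration and pipeline: (phantom | volume) -> segment ->
# quantify -> normalize, with every numeric parameter echoed into the outputs.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a pipeline run configuration
#'
#' YAML (`.yaml`/`.yml`) or JSON file with the fields understood by
#' [run_pipeline()]. The two scientifically sensitive parameters —
#' `erosion$closing_radius_vox` and `erosion$surface_distance_vox` — have no
#' published values and therefore no defaults: a config without them is
#' rejected by name.
#'
#' @param path config file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a named list of configuration entries.
#' @export
as_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list")
  if (is.null(cfg$erosion)) {
    stop("config is missing the 'erosion' section ",
         "(closing_radius_vox, surface_distance_vox)")
  }
  for (p in c("closing_radius_vox", "surface_distance_vox")) {
    if (is.null(cfg$erosion[[p]])) {
      stop("config is missing the mandatory parameter 'erosion$", p,
           "'; it has no default")
    }
  }
  if (is.null(cfg$phantom) && is.null(cfg$input$volume)) {
    stop("config must provide either 'phantom' (spec or spec file) or ",
         "'input$volume'")
  }
  if (is.null(cfg$output$dir)) stop("config is missing 'output$dir'")
  structure(cfg, class = c("run_config", "list"))
}

.log_stage <- function(stage, ...) {
  message(sprintf("[osteoerode:%s] %s", stage, sprintf(...)))
}

.pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full quantification pipeline
#'
#' Stages: obtain a volume (generate a phantom or read from disk), segment
#' it, optionally despeckle, restrict user-supplied per-bone labels,
#' quantify erosion and full pores, normalize against baseline reports, and
#' persist the report plus a machine-readable JSON run summary. The run is
#' deterministic given the config and seed; any stage failure aborts with
#' the stage name.
#'
#' Config fields: `seed`; `phantom` (a [phantom_spec()], a spec-shaped list,
#' or a path to a YAML/JSON spec); `input$volume`, `input$labels` (paths);
#' `segmentation$method` (`"otsu"`/`"fixed"`), `segmentation$fixed_value`,
#' `segmentation$min_voxels`, `segmentation$connectivity`;
#' `erosion$closing_radius_vox`, `erosion$surface_distance_vox` (mandatory),
#' `erosion$connectivity`; `baseline` (report CSV paths); `output$dir`,
#' `output$report`, `output$save_intermediates`.
#'
#' @param config a `run_config`, a config list, or a path to a YAML/JSON
#'   config file.
#' @return The final `erosion_report`, invisibly; artifacts on disk under
#'   `output$dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- as_run_config(config)
  out_dir <- config$output$dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_int <- isTRUE(config$output$save_intermediates)
  summary <- list(package_version = as.character(utils::packageVersion("osteoerode")),
                  config_echo = unclass(config))

  # --- stage: volume -------------------------------------------------------
  truth <- NULL
  vol <- .pipeline_stage("volume", {
    if (!is.null(config$phantom)) {
      spec <- config$phantom
      if (is.character(spec)) spec <- phantom_spec_from_file(spec)
      if (!inherits(spec, "phantom_spec")) {
        if (!is.null(config$seed)) spec$seed <- config$seed
        spec <- do.call(phantom_spec, spec)
      }
      .log_stage("phantom", "generating %s phantom, seed %d",
                 paste(spec$shape, collapse = "x"), spec$seed)
      ph <- generate_phantom(spec)
      truth <- ph$truth
      if (save_int) {
        write_volume(ph$volume, file.path(out_dir, "phantom_volume.nrrd"))
        write_volume(ph$mask, file.path(out_dir, "phantom_true_mask.nrrd"))
        write_ground_truth(ph$truth, file.path(out_dir, "ground_truth.json"))
      }
      ph$volume
    } else {
      .log_stage("volume", "reading %s", config$input$volume)
      v <- read_volume(config$input$volume)
      if (!inherits(v, "voxel_volume")) stop("input volume is not grayscale")
      v
    }
  })

  # --- stage: segmentation -------------------------------------------------
  seg <- config$segmentation %||% list()
  mask <- .pipeline_stage("segment", {
    m <- threshold_bone(vol, method = seg$method %||% "otsu",
                        fixed_value = seg$fixed_value)
    summary$threshold <- attr(m, "threshold")
    if (!is.null(seg$min_voxels)) {
      m <- keep_components(m, seg$min_voxels,
                           connectivity = seg$connectivity %||% 26L)
    }
    m
  })
  if (save_int) write_volume(mask, file.path(out_dir, "mask.nrrd"))

  # --- stage: labels -------------------------------------------------------
  labels <- .pipeline_stage("labels", {
    if (!is.null(config$input$labels)) {
      lb <- read_volume(config$input$labels)
      if (!inherits(lb, "labeled_bones")) stop("labels file is not a label map")
      lb
    } else NULL
  })

  # --- stage: quantify -----------------------------------------------------
  params <- erosion_params(config$erosion$closing_radius_vox,
                           config$erosion$surface_distance_vox,
                           config$erosion$connectivity %||% 26L)
  report <- .pipeline_stage("quantify", {
    .log_stage("quantify", "closing radius %g vox, surface distance %g vox",
               params$closing_radius_vox, params$surface_distance_vox)
    if (save_int) {
      write_volume(fill_pores(mask, params),
                   file.path(out_dir, "filled_mask.nrrd"))
    }
    per_bone_report(mask, labels, params)
  })

  # --- stage: normalize ----------------------------------------------------
  if (!is.null(config$baseline) && length(config$baseline) > 0L) {
    report <- .pipeline_stage("normalize", {
      normalize_report(report, lapply(config$baseline, read_report))
    })
  }

  report_path <- file.path(out_dir, config$output$report %||% "report.csv")
  write_report(report, report_path)

  summary$params <- unclass(params)
  summary$seed <- config$seed
  summary$bone_voxels <- report$bone_voxels[report$label == "whole"]
  summary$erosion_percent_whole <-
    report$erosion_percent[report$label == "whole"]
  summary$full_pore_percent_whole <-
    report$full_pore_percent[report$label == "whole"]
  if (!is.null(truth)) summary$ground_truth <- unclass(truth)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .log_stage("done", "report written to %s", report_path)
  invisible(report)
}
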