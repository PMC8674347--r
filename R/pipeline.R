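# schema of the run configuration: block -> allowed keys
config_schema <- function() {
  list(
    seed = NULL,
    map = c("path", "dialect", "analyzed_fraction", "filter_area"),
    scene = c("width_um", "height_um", "step", "n_random_particles",
              "diameter_range", "n_fibers", "n_residue", "dropout_prob",
              "snr_range", "min_separation_steps", "analyzed_fraction",
              "filter_area", "seed"),
    library = c("path", "n_per_class", "snr_range", "seed"),
    preprocess = c("grid_start", "grid_end", "grid_step", "baseline_lambda",
                   "baseline_p", "baseline_maxit", "smooth_spar"),
    classifier = c("n_trees", "seed", "review_threshold", "drop_review",
                   "merge_stearate_nmp"),
    clustering = c("max_gap", "metric"),
    quantify = c("sample_volume_mL", "blank", "qc_kind",
                 "surface_covered_pct")
  )
}

#' Validate a run configuration
#'
#' A configuration is a named list of parameter blocks (see the CLI
#' documentation); unknown blocks or keys are rejected before any
#' computation so a typo cannot silently fall back to a default.
#'
#' @param config named list, e.g. from [read_config()].
#' @return The config, invisibly, or an error naming the offending key.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  bad_blocks <- setdiff(names(config), names(schema))
  if (length(bad_blocks) > 0L) {
    stop(sprintf("unknown config key(s): %s",
                 paste(bad_blocks, collapse = ", ")), call. = FALSE)
  }
  for (blk in names(config)) {
    allowed <- schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[blk]]), allowed)
    if (length(bad) > 0L) {
      stop(sprintf("unknown key(s) in config block '%s': %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(config)
}

#' Read and validate a YAML run configuration
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path),
                               call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the whole pipeline from a configuration
#'
#' Orchestrates: obtain a map (read from `map$path`, or simulate from the
#' `scene` block), obtain a training library (read from `library$path`, or
#' generate), preprocess both, train the forest, classify every pixel,
#' cluster particles and quantify. Every seed and the full configuration
#' are embedded in the returned report's provenance block, so identical
#' config + seed reproduce the report exactly.
#'
#' @param config validated configuration list (may be empty: a default
#'   synthetic scene is then analyzed end to end).
#' @return A list with `report` (the `quant_report`), `particles`, `pixels`
#'   (per-pixel classifications), `model` and, for simulated scenes,
#'   `truth`.
#' @export
run_pipeline <- function(config = list()) {
  validate_config(config)
  seed <- as.integer(config$seed %||% 1L)

  pp <- do.call(preprocess_params, config$preprocess %||% list())

  truth <- NULL
  if (!is.null(config$map$path)) {
    map <- read_map(config$map$path,
                    dialect = config$map$dialect %||% "csv",
                    analyzed_fraction = config$map$analyzed_fraction %||% 0.5,
                    filter_area = config$map$filter_area %||% 14)
  } else {
    scene_args <- config$scene %||% list()
    scene_args$seed <- scene_args$seed %||% seed
    sim <- generate_map(do.call(scene_spec, scene_args))
    map <- sim$map
    truth <- sim
  }

  if (!is.null(config$library$path)) {
    lib <- read_library(config$library$path)
  } else {
    lib <- generate_training_library(
      n_per_class = config$library$n_per_class %||% 50,
      snr_range = config$library$snr_range %||% c(15, 40),
      seed = config$library$seed %||% (seed + 1L))
  }

  lib_pp <- preprocess_library(lib, pp)
  model <- train_classifier(lib_pp,
                            n_trees = config$classifier$n_trees %||% 1500,
                            seed = config$classifier$seed %||% (seed + 2L))

  map_pp <- preprocess_map(map, pp)
  pixels <- predict(model, map_pp,
                    review_threshold =
                      config$classifier$review_threshold %||% 0.5)

  exclude <- "NMP"
  if (isTRUE(config$classifier$merge_stearate_nmp)) {
    exclude <- c(exclude, "stearate")
  }
  particles <- cluster_particles(
    pixels, step = map$step,
    max_gap = config$clustering$max_gap %||% 2,
    exclude = exclude,
    metric = config$clustering$metric %||% "chebyshev",
    map = map_pp)

  q <- config$quantify %||% list()
  blank <- q$blank
  if (!is.null(blank)) blank <- unlist(blank)
  report <- quantify_particles(
    particles,
    analyzed_fraction = map$analyzed_fraction,
    sample_volume_mL = q$sample_volume_mL %||% 25,
    blank = blank,
    filter_area = map$filter_area,
    qc_kind = q$qc_kind %||% "sample",
    surface_covered_pct = q$surface_covered_pct %||% NA_real_,
    drop_review = isTRUE(config$classifier$drop_review),
    review_confidence = config$classifier$review_threshold %||% 0.5,
    config = config,
    seeds = list(run = seed,
                 library = config$library$seed %||% (seed + 1L),
                 classifier = config$classifier$seed %||% (seed + 2L),
                 oob_error = model$oob_error))

  list(report = report, particles = particles, pixels = pixels,
       model = model, truth = truth)
}
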