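#' Configure an end-to-end pipeline run
#'
#' Bundles every stage's settings: the synthetic scene (or an external scene
#' TIFF), the weather series (or an external CSV), index constants, the
#' classifier and forecaster configurations, the rule set, and one global
#' seed from which every stage's RNG stream is derived. The final `horizon`
#' days of the weather series are always held out as verification data: the
#' forecaster trains on the earlier days and is scored against the held-out
#' tail.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Global integer seed.
#' @param scene List of [scene_spec()] arguments for the simulated scene, or
#'   a list with `path` (scene TIFF) and `truth_path` (label TIFF) to skip
#'   simulation.
#' @param weather List of [weather_sim_params()] arguments, or a list with
#'   `path` to an external station CSV.
#' @param horizon Forecast/verification horizon in days.
#' @param classifier List of [classifier_config()] overrides.
#' @param forecaster List of [forecaster_config()] overrides.
#' @param evi [evi_constants()].
#' @param ndvi_as_printed Use the literal reciprocal NDVI variant.
#' @param rules `"default"`, `"text_rice"`, or a path to a YAML/JSON rule
#'   file.
#' @param land_class_source `"predicted"` (modal class of the predicted map)
#'   or `"truth"` (modal class of the ground truth).
#' @param force_land_class Optional class overriding the derived land class
#'   (e.g. to probe the gating rule).
#' @param verbose Log stage progress to stderr.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir = tempfile("cropsense_run_"),
                            seed = 1,
                            scene = list(),
                            weather = list(n_days = 3 * 365 + 30),
                            horizon = 30,
                            classifier = list(),
                            forecaster = list(),
                            evi = evi_constants(),
                            ndvi_as_printed = FALSE,
                            rules = "default",
                            land_class_source = c("predicted", "truth"),
                            force_land_class = NULL,
                            verbose = TRUE) {
  land_class_source <- match.arg(land_class_source)
  horizon <- assert_count(horizon, "horizon", min = 1L)
  if (!is.null(force_land_class)) assert_land_class(force_land_class)
  structure(
    list(
      out_dir = out_dir, seed = seed, scene = scene, weather = weather,
      horizon = horizon, classifier = classifier, forecaster = forecaster,
      evi = evi, ndvi_as_printed = isTRUE(ndvi_as_printed), rules = rules,
      land_class_source = land_class_source,
      force_land_class = force_land_class, verbose = isTRUE(verbose)
    ),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `evi` may be
#' given as a list of `G`, `C1`, `C2`, `L`.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after reading.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$evi)) raw$evi <- do.call(evi_constants, raw$evi)
  args <- modifyList(raw, list(...))
  do.call(pipeline_config, args)
}

resolve_rules <- function(rules) {
  if (inherits(rules, "crop_rules")) {
    return(validate_crop_rules(rules))
  }
  if (identical(rules, "default")) {
    return(default_crop_rules())
  }
  if (identical(rules, "text_rice")) {
    return(text_rice_rule())
  }
  load_crop_rules(rules)
}

modal_class <- function(map) {
  counts <- table(factor(map$labels[!map$nodata_mask], levels = land_classes()))
  names(counts)[which.max(counts)]
}

stage_log <- function(verbose, stage, msg) {
  if (verbose) inform(sprintf("[%s] %s", stage, msg))
}

#' Run the full crop-advisory pipeline
#'
#' Executes, in order: scene simulation (or load), spectral-index
#' computation and stacking, classifier training and full-map prediction,
#' weather simulation (or load), forecaster training, multi-day forecast
#' with persistence reference, rule-based crop recommendation over the
#' forecast horizon, and evaluation (classification report against the
#' scene truth; forecast MAE/RMSE against the held-out days). All artifacts
#' are written under `config$out_dir` and listed in the returned manifest
#' (also written as `manifest.json`). A fixed config and seed reproduce
#' every artifact byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @return A `run_manifest` list: config snapshot, seed, per-stage status,
#'   artifact paths, and the headline results (`classification_accuracy`,
#'   `forecast_errors`, `recommendation_summary`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config.", class = "cropsense_validation_error")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- list()
  stages <- list()
  run_stage <- function(name, fun) {
    stage_log(config$verbose, name, "started")
    t0 <- Sys.time()
    result <- tryCatch(fun(), error = function(e) {
      abort(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = "cropsense_stage_error", parent = e
      )
    })
    stages[[name]] <<- list(
      status = "ok",
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    )
    stage_log(config$verbose, name, "done")
    result
  }
  path_of <- function(name) file.path(config$out_dir, name)

  # ---- scene ----
  scene <- run_stage("scene", function() {
    if (!is.null(config$scene$path)) {
      list(
        bands = read_scene_tiff(config$scene$path),
        truth = read_map_tiff(config$scene$truth_path)
      )
    } else {
      args <- modifyList(
        list(seed = derive_seed(config$seed, 1)),
        config$scene
      )
      generate_scene(do.call(scene_spec, args))
    }
  })
  art$scene <- path_of("scene.tif")
  write_scene_tiff(scene$bands, art$scene)
  art$truth <- path_of("truth.tif")
  write_map_tiff(scene$truth, art$truth)

  # ---- indices ----
  stack <- run_stage("indices", function() {
    compute_index_stack(scene$bands, config$evi, config$ndvi_as_printed)
  })
  art$stack <- path_of("stack.tif")
  write_stack_tiff(stack, art$stack)

  # ---- classifier ----
  cls_cfg <- do.call(classifier_config, modifyList(
    list(seed = derive_seed(config$seed, 2)), config$classifier
  ))
  model <- run_stage("train-classifier", function() {
    ds <- extract_patches(stack, scene$truth, cls_cfg$patch_size)
    train_classifier(ds, cls_cfg, scaler = stack$scaler)
  })
  art$classifier_history <- path_of("classifier_history.csv")
  readr::write_csv(model$history, art$classifier_history)
  art$classifier_checkpoint <- path_of("classifier.rds")
  save_checkpoint(model, art$classifier_checkpoint)

  map <- run_stage("classify", function() predict_map(model, stack))
  art$map <- path_of("suitability_map.tif")
  write_map_tiff(map, art$map)

  # ---- weather ----
  weather <- run_stage("weather", function() {
    if (!is.null(config$weather$path)) {
      read_weather_csv(config$weather$path)
    } else {
      args <- modifyList(
        list(seed = derive_seed(config$seed, 3)),
        config$weather
      )
      generate_weather(do.call(weather_sim_params, args))
    }
  })
  if (nrow(weather) <= config$horizon + 30) {
    abort("weather series too short for the configured horizon.",
      class = "cropsense_validation_error"
    )
  }
  art$weather <- path_of("weather.csv")
  write_weather_csv(weather, art$weather)

  n_obs <- nrow(weather) - config$horizon
  train_series <- weather[seq_len(n_obs), ]
  held_out <- weather[(n_obs + 1):nrow(weather), ]

  fc_cfg <- do.call(forecaster_config, modifyList(
    list(seed = derive_seed(config$seed, 4), horizon = config$horizon),
    config$forecaster
  ))
  forecaster <- run_stage("train-forecaster", function() {
    train_forecaster(train_series, fc_cfg)
  })
  art$forecaster_history <- path_of("forecaster_history.csv")
  readr::write_csv(forecaster$history, art$forecaster_history)
  art$forecaster_checkpoint <- path_of("forecaster.rds")
  save_checkpoint(forecaster, art$forecaster_checkpoint)
  art$scaler <- path_of("forecaster_scaler.json")
  write_scaler_json(forecaster$scaler, art$scaler)

  window <- train_series[(n_obs - fc_cfg$window_length + 1):n_obs, ]
  fc <- run_stage("forecast", function() {
    forecast_weather(forecaster, window, config$horizon)
  })
  pers <- persistence_baseline(window, config$horizon)
  art$forecast <- path_of("forecast.csv")
  write_weather_csv(fc, art$forecast)
  art$persistence <- path_of("persistence.csv")
  write_weather_csv(pers, art$persistence)

  # ---- recommendation ----
  rules <- resolve_rules(config$rules)
  land_class <- config$force_land_class %||% switch(config$land_class_source,
    predicted = modal_class(map),
    truth = modal_class(scene$truth)
  )
  recs <- run_stage("recommend", function() {
    recommend_series(fc, land_class, rules)
  })
  art$recommendations <- path_of("recommendations.csv")
  readr::write_csv(
    dplyr::mutate(
      as_tibble(recs),
      matched_crops = purrr::map_chr(.data$matched_crops, paste, collapse = ";")
    ),
    art$recommendations
  )

  # ---- evaluation ----
  evaluation <- run_stage("evaluate", function() {
    keep <- !(scene$truth$nodata_mask | map$nodata_mask)
    cm <- confusion_matrix(scene$truth$labels[keep], map$labels[keep])
    report <- classification_report(cm)
    fe <- purrr::map_dfr(forecast_features(), function(v) {
      dplyr::bind_cols(
        tibble(variable = v, model = c("lstm", "persistence")),
        dplyr::bind_rows(
          regression_errors(held_out[[v]], fc[[v]]),
          regression_errors(held_out[[v]], pers[[v]])
        )
      )
    })
    list(cm = cm, report = report, forecast_errors = fe)
  })
  art$classification_report <- path_of("classification_report.csv")
  readr::write_csv(as_tibble(evaluation$report), art$classification_report)
  art$confusion_matrix <- path_of("confusion_matrix.csv")
  readr::write_csv(tidy(evaluation$cm), art$confusion_matrix)
  art$forecast_errors <- path_of("forecast_errors.csv")
  readr::write_csv(evaluation$forecast_errors, art$forecast_errors)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cropsense")),
    seed = config$seed,
    config = serialize_config(config),
    land_class_used = land_class,
    stages = stages,
    artifacts = art,
    classification_accuracy = attr(evaluation$report, "accuracy"),
    forecast_errors = evaluation$forecast_errors,
    recommendation_summary = attr(recs, "summary")
  )
  art$manifest <- path_of("manifest.json")
  jsonlite::write_json(manifest, art$manifest, auto_unbox = TRUE, digits = NA)
  manifest$artifacts <- art
  structure(manifest, class = "run_manifest")
}

serialize_config <- function(config) {
  plain <- unclass(config)
  plain$evi <- unclass(plain$evi)
  if (inherits(plain$rules, "crop_rules")) plain$rules <- as.data.frame(plain$rules)
  plain
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf(
    "<run_manifest: seed %s, land class %s, accuracy %.3f, %d artifacts>\n",
    x$seed, x$land_class_used, x$classification_accuracy, length(x$artifacts)
  ))
  invisible(x)
}
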