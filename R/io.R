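# File formats: weather tables travel as CSV in the station schema
# (Time, Temperature.2M, relHumidity.2M, totPrecips, Pressure); rasters as
# multi-page float TIFF with a JSON sidecar holding band names, georeference
# and the class encoding (0 = NOT_SUITABLE, 1 = LOW, 2 = HIGH, nodata 255);
# scalers and manifests as JSON.

weather_schema_map <- function() {
  c(
    time = "Time",
    temperature_2m = "Temperature.2M",
    rel_humidity_2m = "relHumidity.2M",
    total_precip = "totPrecips",
    pressure = "Pressure"
  )
}

#' Write a weather series as CSV
#'
#' Uses the station-record header `Time, Temperature.2M, relHumidity.2M,
#' totPrecips, Pressure`; dates are written ISO (YYYY-MM-DD).
#'
#' @param series A weather series tibble.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(series, path) {
  series <- validate_weather_series(series)
  out <- series[weather_columns()]
  names(out) <- unname(weather_schema_map()[names(out)])
  readr::write_csv(as_tibble(out), path)
  invisible(path)
}

#' Read a weather series from CSV
#'
#' Accepts the station-record header (`Time, Temperature.2M, ...`), with
#' dates either ISO or `m/d/Y`.
#'
#' @param path CSV path.
#' @return A validated weather series tibble.
#' @export
read_weather_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  map <- weather_schema_map()
  missing <- setdiff(unname(map), names(raw))
  if (length(missing)) {
    abort(
      paste0("weather CSV missing columns: ", paste(missing, collapse = ", ")),
      class = "cropsense_validation_error"
    )
  }
  out <- raw[unname(map)]
  names(out) <- names(map)
  if (!inherits(out$time, "Date")) {
    parsed <- suppressWarnings(as.Date(out$time, tryFormats = c(
      "%Y-%m-%d", "%m/%d/%Y", "%d/%m/%Y"
    )))
    if (any(is.na(parsed))) {
      abort("could not parse dates in the Time column.",
        class = "cropsense_validation_error"
      )
    }
    out$time <- parsed
  }
  validate_weather_series(out)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a scene's band rasters as multi-page TIFF
#'
#' One 32-bit float page per band; band ids, the nodata mask convention and
#' the georeference go to a JSON sidecar (`<path>.json`).
#'
#' @param bands Named list of [band_raster()] objects on one grid.
#' @param path Destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_scene_tiff <- function(bands, path) {
  pages <- lapply(bands, function(b) {
    v <- b$values
    v[b$nodata_mask] <- 0
    v
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(
      kind = "scene",
      band_ids = names(bands),
      georef = bands[[1]]$georef,
      nodata = "mask stored as extra considerations; zeros where masked"
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a scene written by [write_scene_tiff()]
#'
#' @param path `.tif` path with its JSON sidecar alongside.
#' @return Named list of [band_raster()] objects.
#' @export
read_scene_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  georef <- list(
    origin = as.numeric(meta$georef$origin),
    pixel_size = as.numeric(meta$georef$pixel_size),
    crs = as.character(meta$georef$crs)
  )
  out <- purrr::map2(
    pages, meta$band_ids,
    function(v, id) band_raster(id, v, georef = georef)
  )
  names(out) <- meta$band_ids
  out
}

#' Write an index stack as multi-page TIFF
#'
#' Channel names, per-channel scaler parameters and georeference go to the
#' JSON sidecar so inference can reuse the training statistics.
#'
#' @param stack An `index_stack`.
#' @param path Destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  pages <- lapply(seq_along(stack$channel_names), function(i) {
    v <- stack$values[, , i]
    v[stack$nodata_mask | is.na(v)] <- 0
    v
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(
      kind = "index_stack",
      channel_names = stack$channel_names,
      scaler = stack$scaler,
      georef = stack$georef,
      mask = which(stack$nodata_mask) # linear indices, column-major
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an index stack written by [write_stack_tiff()]
#'
#' @param path `.tif` path with sidecar.
#' @return An `index_stack`.
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mask <- matrix(FALSE, nrow(pages[[1]]), ncol(pages[[1]]))
  mask[as.integer(meta$mask)] <- TRUE
  scaler <- purrr::map(meta$scaler, function(s) {
    list(min = s$min, max = s$max, degenerate = isTRUE(s$degenerate))
  })
  georef <- list(
    origin = as.numeric(meta$georef$origin),
    pixel_size = as.numeric(meta$georef$pixel_size),
    crs = as.character(meta$georef$crs)
  )
  layers <- purrr::map2(pages, meta$channel_names, function(v, nm) {
    v[mask] <- NA_real_
    index_layer(nm, v, mask, georef)
  })
  stack_layers(layers, scaler = scaler)
}

#' Write a suitability map as TIFF
#'
#' Single 8-bit page with the class encoding 0 = NOT_SUITABLE, 1 = LOW,
#' 2 = HIGH, 255 = nodata; probability channels, when present, go to an
#' accompanying 3-page float TIFF (`<path>` with suffix `_prob`).
#'
#' @param map A [suitability_map()].
#' @param path Destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  codes <- matrix(class_to_code(map$labels), nrow(map$labels), ncol(map$labels))
  codes[map$nodata_mask] <- 255L
  tiff::writeTIFF(codes / 255, path, bits.per.sample = 8, reduce = FALSE)
  if (!is.null(map$probabilities)) {
    prob_path <- sub("(\\.tiff?)$", "_prob\\1", path)
    pages <- lapply(1:3, function(k) {
      v <- map$probabilities[, , k]
      v[is.na(v)] <- 0
      v
    })
    tiff::writeTIFF(pages, prob_path, bits.per.sample = 32, reduce = FALSE)
  }
  jsonlite::write_json(
    list(
      kind = "suitability_map",
      encoding = list(NOT_SUITABLE = 0, LOW = 1, HIGH = 2, nodata = 255),
      class_order = land_classes(),
      georef = map$georef
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a suitability map written by [write_map_tiff()]
#'
#' @param path `.tif` path with sidecar.
#' @return A [suitability_map()] (labels only).
#' @export
read_map_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  v <- tiff::readTIFF(path, all = FALSE)
  codes <- round(v * 255)
  mask <- codes == 255
  codes[mask] <- 0
  georef <- list(
    origin = as.numeric(meta$georef$origin),
    pixel_size = as.numeric(meta$georef$pixel_size),
    crs = as.character(meta$georef$crs)
  )
  suitability_map(codes, nodata_mask = mask, georef = georef)
}

#' Save or load a fitted model checkpoint
#'
#' Single-file checkpoints for trained classifiers and forecasters (RDS).
#'
#' @param model A `suitability_model` or `weather_forecaster`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Write or read feature-scaler parameters as JSON
#'
#' @param scaler A scaler (per-channel list or `feature_scaler`).
#' @param path JSON path.
#' @return `path` (write) or the scaler (read).
#' @export
write_scaler_json <- function(scaler, path) {
  jsonlite::write_json(unclass(scaler), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaler_json
#' @export
read_scaler_json <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(s$min) && !is.null(s$degenerate)) {
    structure(
      list(
        min = unlist(s$min), max = unlist(s$max),
        degenerate = unlist(s$degenerate)
      ),
      class = "feature_scaler"
    )
  } else {
    s
  }
}
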