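#' Canonical index channel order
#'
#' The fixed channel order used in every index stack.
#'
#' @return Character vector of the six index names.
#' @export
index_names <- function() c("NDVI", "NDWI", "MOISTURE", "EVI", "NDSI", "GNDVI")

#' Enhanced Vegetation Index constants
#'
#' Gain and aerosol-resistance constants for EVI,
#' `G * (NIR - Red) / (NIR + C1 * Red - C2 * Blue + L)`. Defaults are the
#' standard MODIS/Sentinel-2 values G = 2.5, C1 = 6, C2 = 7.5, L = 1.
#'
#' @param G Gain factor.
#' @param C1,C2 Aerosol-resistance coefficients (red, blue).
#' @param L Canopy background adjustment.
#' @return An `evi_constants` object.
#' @export
evi_constants <- function(G = 2.5, C1 = 6, C2 = 7.5, L = 1) {
  for (nm in c("G", "C1", "C2", "L")) {
    assert_scalar_number(get(nm), nm)
  }
  structure(list(G = G, C1 = C1, C2 = C2, L = L), class = "evi_constants")
}

#' Construct an index layer
#'
#' @param index_name Name of the spectral index.
#' @param values Numeric matrix.
#' @param nodata_mask Logical matrix.
#' @param georef Georeference metadata.
#' @return An `index_layer` object.
#' @export
index_layer <- function(index_name, values, nodata_mask = NULL,
                        georef = default_georef()) {
  if (!is.matrix(values)) {
    abort("`values` must be a matrix.", class = "cropsense_validation_error")
  }
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, nrow(values), ncol(values))
  assert_same_dim(values, nodata_mask, "values and nodata_mask")
  structure(
    list(
      index_name = index_name, values = values,
      nodata_mask = nodata_mask, georef = georef
    ),
    class = "index_layer"
  )
}

#' @export
print.index_layer <- function(x, ...) {
  v <- x$values[!x$nodata_mask]
  cat(sprintf(
    "<index_layer %s: %d x %d, range [%.3f, %.3f], %d%% masked>\n",
    x$index_name, nrow(x$values), ncol(x$values),
    suppressWarnings(min(v)), suppressWarnings(max(v)),
    round(100 * mean(x$nodata_mask))
  ))
  invisible(x)
}

#' @export
dim.index_layer <- function(x) dim(x$values)

#' Normalized difference of two reflectance grids
#'
#' Computes `(a - b) / (a + b)` elementwise — the shared form of NDVI, NDWI,
#' NDSI, GNDVI and the moisture index. Pixels where `a + b == 0` are masked
#' rather than given an arbitrary value; on nonnegative inputs the unmasked
#' result lies in \[-1, 1\].
#'
#' @param a,b Aligned numeric matrices (same dimensions).
#' @return List with `values` (matrix) and `mask` (logical matrix of pixels
#'   masked because of a zero denominator).
#' @export
#' @examples
#' normalized_difference(matrix(0.8), matrix(0.2))$values
normalized_difference <- function(a, b) {
  if (!is.matrix(a)) a <- as.matrix(a)
  if (!is.matrix(b)) b <- as.matrix(b)
  assert_same_dim(a, b, "index input grids")
  denom <- a + b
  zero <- is.finite(denom) & denom == 0
  vals <- (a - b) / denom
  vals[zero] <- NA_real_
  list(values = vals, mask = zero | !is.finite(a) | !is.finite(b))
}

# bands required per index, as equation symbols
index_requirements <- function() {
  list(
    NDVI = c("NIR", "Red"),
    NDWI = c("Green", "NIR"),
    MOISTURE = c("narrow", "SWIR"),
    EVI = c("NIR", "Red", "Blue"),
    NDSI = c("Green", "SWIR"),
    GNDVI = c("NIR", "Green")
  )
}

get_symbol_band <- function(bands, symbol) {
  id <- band_symbols()[[symbol]]
  if (is.null(bands[[id]])) {
    abort(
      sprintf("band %s (%s) required but absent from the scene.", id, symbol),
      class = "cropsense_config_error"
    )
  }
  bands[[id]]
}

#' Compute a spectral index layer
#'
#' Evaluates one of the six indices from a scene's band collection:
#' * NDVI `(NIR - Red)/(NIR + Red)` (set `ndvi_as_printed = TRUE` for the
#'   reciprocal form `(NIR + Red)/(NIR - Red)`, an unbounded variant kept
#'   for completeness),
#' * NDWI `(Green - NIR)/(Green + NIR)`,
#' * MOISTURE `(narrowNIR - SWIR)/(narrowNIR + SWIR)`,
#' * EVI `G (NIR - Red)/(NIR + C1 Red - C2 Blue + L)`,
#' * NDSI `(Green - SWIR)/(Green + SWIR)`,
#' * GNDVI `(NIR - Green)/(NIR + Green)`.
#'
#' Band symbols map to Sentinel-2 ids as Blue = B02, Green = B03, Red = B04,
#' NIR = B08, narrow NIR = B8A, SWIR = B11. Zero-denominator pixels are
#' masked; input nodata masks propagate.
#'
#' @param name One of [index_names()].
#' @param bands Named list of [band_raster()] objects keyed by band id.
#' @param constants [evi_constants()] used for EVI.
#' @param ndvi_as_printed If `TRUE`, compute the literal reciprocal NDVI form.
#' @return An [index_layer()].
#' @export
compute_index <- function(name, bands, constants = evi_constants(),
                          ndvi_as_printed = FALSE) {
  name <- toupper(name)
  if (!name %in% index_names()) {
    abort(
      paste0("unknown index: ", name),
      class = "cropsense_config_error"
    )
  }
  req <- index_requirements()[[name]]
  missing_ids <- band_symbols()[req][!band_symbols()[req] %in% names(bands)]
  if (length(missing_ids)) {
    abort(
      paste0("missing band(s): ", paste(missing_ids, collapse = ", ")),
      class = "cropsense_config_error"
    )
  }
  grids <- lapply(req, function(s) get_symbol_band(bands, s)$values)
  names(grids) <- req
  in_mask <- Reduce(`|`, lapply(req, function(s) get_symbol_band(bands, s)$nodata_mask))
  georef <- get_symbol_band(bands, req[1])$georef

  if (name == "EVI") {
    denom <- grids$NIR + constants$C1 * grids$Red - constants$C2 * grids$Blue + constants$L
    zero <- is.finite(denom) & denom == 0
    vals <- constants$G * (grids$NIR - grids$Red) / denom
    vals[zero] <- NA_real_
    return(index_layer("EVI", vals, in_mask | zero, georef))
  }
  if (name == "NDVI" && ndvi_as_printed) {
    denom <- grids$NIR - grids$Red
    zero <- is.finite(denom) & denom == 0
    vals <- (grids$NIR + grids$Red) / denom
    vals[zero] <- NA_real_
    return(index_layer("NDVI", vals, in_mask | zero, georef))
  }
  pair <- switch(name,
    NDVI = list(grids$NIR, grids$Red),
    NDWI = list(grids$Green, grids$NIR),
    MOISTURE = list(grids$narrow, grids$SWIR),
    NDSI = list(grids$Green, grids$SWIR),
    GNDVI = list(grids$NIR, grids$Green)
  )
  nd <- normalized_difference(pair[[1]], pair[[2]])
  index_layer(name, nd$values, in_mask | nd$mask, georef)
}

#' Min-max normalize an index layer
#'
#' Rescales a layer to \[0, 1\] with `(x - min)/(max - min)`. When `params`
#' is supplied (e.g. the statistics fitted on training data), those bounds
#' are reused and out-of-range values are clipped to \[0, 1\]; otherwise the
#' layer's own unmasked min and max are used. A constant layer (max == min)
#' maps to all zeros and is flagged degenerate.
#'
#' @param layer An [index_layer()].
#' @param params Optional list with `min` and `max` to reuse.
#' @return List with `layer` (normalized [index_layer()]) and `params`
#'   (list `min`, `max`, `degenerate`) for later reuse or denormalization.
#' @export
minmax_normalize <- function(layer, params = NULL) {
  v <- layer$values[!layer$nodata_mask]
  if (!length(v)) {
    abort("cannot normalize a fully masked layer.",
      class = "cropsense_validation_error"
    )
  }
  if (is.null(params)) {
    params <- list(min = min(v), max = max(v))
  }
  if (params$max < params$min) {
    abort("scaler max must be >= min.", class = "cropsense_validation_error")
  }
  degenerate <- params$max == params$min
  if (degenerate) {
    warn(sprintf("layer %s is constant; normalized to all zeros.", layer$index_name))
    vals <- matrix(0, nrow(layer$values), ncol(layer$values))
  } else {
    vals <- (layer$values - params$min) / (params$max - params$min)
    vals <- pmin(pmax(vals, 0), 1)
  }
  vals[layer$nodata_mask] <- NA_real_
  list(
    layer = index_layer(layer$index_name, vals, layer$nodata_mask, layer$georef),
    params = list(min = params$min, max = params$max, degenerate = degenerate)
  )
}

#' Invert a min-max normalization
#'
#' @param values Normalized values in \[0, 1\].
#' @param params Scaler params from [minmax_normalize()].
#' @return Values on the original scale.
#' @export
minmax_denormalize <- function(values, params) {
  if (isTRUE(params$degenerate)) {
    return(values * 0 + params$min)
  }
  values * (params$max - params$min) + params$min
}

#' Stack six normalized index layers into the classifier input
#'
#' Layers must arrive in the canonical channel order (NDVI, NDWI, MOISTURE,
#' EVI, NDSI, GNDVI) on one common grid. The stack's nodata mask is the
#' union of the layers' masks — stacking never unmasks a pixel.
#'
#' @param layers List of six normalized [index_layer()] objects.
#' @param scaler Optional named list of per-channel scaler params, recorded
#'   on the stack so inference can reuse training statistics.
#' @return An `index_stack` with `values` (rows x cols x 6 array),
#'   `channel_names`, `nodata_mask`, `scaler`, `georef`.
#' @export
stack_layers <- function(layers, scaler = NULL) {
  if (length(layers) != 6) {
    abort("exactly six index layers are required.",
      class = "cropsense_validation_error"
    )
  }
  got <- vapply(layers, function(l) l$index_name, character(1))
  if (!identical(got, index_names())) {
    abort(
      paste0(
        "layers must arrive in canonical order ",
        paste(index_names(), collapse = ", "), "; got ",
        paste(got, collapse = ", ")
      ),
      class = "cropsense_validation_error"
    )
  }
  d <- dim(layers[[1]]$values)
  for (l in layers) assert_same_dim(l$values, layers[[1]]$values, "index layers")
  vals <- array(NA_real_, c(d[1], d[2], 6))
  mask <- matrix(FALSE, d[1], d[2])
  for (i in seq_along(layers)) {
    vals[, , i] <- layers[[i]]$values
    mask <- mask | layers[[i]]$nodata_mask
  }
  vals[array(mask, c(d[1], d[2], 6))] <- NA_real_
  if (any(!mask)) {
    rng <- range(vals, na.rm = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
      abort("stacked channels must be normalized to [0, 1] first.",
        class = "cropsense_validation_error"
      )
    }
  }
  structure(
    list(
      channel_names = index_names(),
      values = vals,
      nodata_mask = mask,
      scaler = scaler,
      georef = layers[[1]]$georef
    ),
    class = "index_stack"
  )
}

#' @export
print.index_stack <- function(x, ...) {
  cat(sprintf(
    "<index_stack %d x %d x %d [%s], %d%% masked>\n",
    dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
    paste(x$channel_names, collapse = ", "),
    round(100 * mean(x$nodata_mask))
  ))
  invisible(x)
}

#' @export
dim.index_stack <- function(x) dim(x$values)

#' Extract one channel of an index stack as a layer
#'
#' @param stack An `index_stack`.
#' @param name Channel name.
#' @return An [index_layer()].
#' @export
stack_channel <- function(stack, name) {
  i <- match(name, stack$channel_names)
  if (is.na(i)) {
    abort(paste0("no channel named ", name), class = "cropsense_validation_error")
  }
  index_layer(name, stack$values[, , i], stack$nodata_mask, stack$georef)
}

#' Compute the full normalized index stack for a scene
#'
#' Convenience wrapper: computes the six indices, min-max normalizes each
#' (reusing `scaler` when given, e.g. at inference time), and stacks them in
#' canonical order.
#'
#' @param bands Named list of [band_raster()] objects.
#' @param constants [evi_constants()].
#' @param ndvi_as_printed Use the literal reciprocal NDVI form.
#' @param scaler Optional named list of per-channel scaler params to reuse.
#' @return An `index_stack`.
#' @export
compute_index_stack <- function(bands, constants = evi_constants(),
                                ndvi_as_printed = FALSE, scaler = NULL) {
  layers <- list()
  params <- list()
  for (nm in index_names()) {
    layer <- compute_index(nm, bands, constants, ndvi_as_printed)
    norm <- minmax_normalize(layer, params = scaler[[nm]])
    layers[[nm]] <- norm$layer
    params[[nm]] <- norm$params
  }
  stack_layers(unname(layers), scaler = params)
}

#' Composite pixel band sum
#'
#' Sum of the three 8-bit display-band values at one pixel — the per-class
#' composite signature used when inspecting rendered classification maps
#' (e.g. a high-agriculture pixel (19, 237, 66) sums to 322).
#'
#' @param values Numeric vector of exactly three nonnegative 8-bit values.
#' @return Integer sum.
#' @export
#' @examples
#' class_pixel_band_sum(c(19, 237, 66))
class_pixel_band_sum <- function(values) {
  if (length(values) != 3) {
    abort("exactly three display-band values are required.",
      class = "cropsense_validation_error"
    )
  }
  if (any(values < 0 | values > 255 | values != as.integer(values))) {
    abort("display-band values must be integers in [0, 255].",
      class = "cropsense_validation_error"
    )
  }
  as.integer(sum(values))
}

#' Tidy an index stack into a long tibble
#'
#' @param x An `index_stack`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `index`, `value`, `masked`.
#' @method tidy index_stack
#' @export
tidy.index_stack <- function(x, ...) {
  d <- dim(x$values)
  tibble(
    row = rep(rep(seq_len(d[1]), times = d[2]), times = d[3]),
    col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    index = factor(rep(x$channel_names, each = d[1] * d[2]), levels = index_names()),
    value = as.vector(x$values),
    masked = rep(as.vector(x$nodata_mask), times = d[3])
  )
}

#' Plot the channels of an index stack
#'
#' @param object An `index_stack`.
#' @param ... Unused.
#' @return A ggplot object faceted by index.
#' @method autoplot index_stack
#' @export
autoplot.index_stack <- function(object, ...) {
  df <- dplyr::filter(tidy(object), !.data$masked)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~index) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "value") +
    ggplot2::theme_minimal()
}
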