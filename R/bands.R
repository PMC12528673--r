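#' Sentinel-2 band metadata
#'
#' Central wavelengths, bandwidths and nominal spatial resolutions for the
#' Sentinel-2A band set (B01-B12 including B8A). Values are used as raster
#' metadata only: all synthetic scenes are generated on one common grid.
#'
#' @return A tibble with columns `band_id`, `central_wavelength_nm`,
#'   `bandwidth_nm`, `resolution_m`.
#' @export
#' @examples
#' sentinel2_bands()
sentinel2_bands <- function() {
  tibble(
    band_id = c(
      "B01", "B02", "B03", "B04", "B05", "B06", "B07",
      "B08", "B8A", "B09", "B10", "B11", "B12"
    ),
    central_wavelength_nm = c(
      442.7, 492.4, 559.8, 664.6, 704.1, 740.5, 782.8,
      832.8, 864.7, 945.1, 1373.5, 1613.7, 2202.4
    ),
    bandwidth_nm = c(21, 66, 36, 31, 15, 15, 20, 106, 21, 20, 31, 91, 175),
    resolution_m = c(60, 10, 10, 10, 20, 20, 20, 10, 20, 60, 60, 20, 20)
  )
}

#' Default spectral band set
#'
#' The six bands required by the spectral-index equations, under the standard
#' Sentinel-2 colour mapping: Blue = B02, Green = B03, Red = B04, NIR = B08,
#' narrow NIR = B8A, SWIR = B11.
#'
#' @return Character vector of band ids.
#' @export
default_band_set <- function() c("B02", "B03", "B04", "B08", "B8A", "B11")

# symbol -> band id mapping used by the index equations
band_symbols <- function() {
  c(
    Blue = "B02", Green = "B03", Red = "B04",
    NIR = "B08", narrow = "B8A", SWIR = "B11"
  )
}

#' Construct a band raster
#'
#' A single spectral band on a regular grid: a numeric matrix of surface
#' reflectance in \[0, 1\] plus a logical nodata mask and light georeference
#' metadata (origin, pixel size, CRS string). Wavelength/bandwidth/resolution
#' metadata are filled from [sentinel2_bands()] when the id is known.
#'
#' @param band_id Band identifier (e.g. `"B04"`).
#' @param values Numeric matrix of reflectance values.
#' @param nodata_mask Logical matrix, `TRUE` where the pixel is invalid.
#' @param georef Named list with `origin` (x, y), `pixel_size`, `crs`.
#' @return A `band_raster` object.
#' @export
band_raster <- function(band_id, values,
                        nodata_mask = NULL,
                        georef = default_georef()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "cropsense_validation_error")
  }
  if (any(dim(values) <= 0)) {
    abort("grid dimensions must be positive.", class = "cropsense_validation_error")
  }
  if (is.null(nodata_mask)) {
    nodata_mask <- matrix(FALSE, nrow(values), ncol(values))
  }
  assert_same_dim(values, nodata_mask, "values and nodata_mask")
  if (any(!is.finite(values[!nodata_mask]))) {
    abort("unmasked reflectance values must be finite.",
      class = "cropsense_validation_error"
    )
  }
  meta <- dplyr::filter(sentinel2_bands(), .data$band_id == !!band_id)
  structure(
    list(
      band_id = band_id,
      values = values,
      nodata_mask = nodata_mask,
      central_wavelength_nm = if (nrow(meta)) meta$central_wavelength_nm else NA_real_,
      bandwidth_nm = if (nrow(meta)) meta$bandwidth_nm else NA_real_,
      resolution_m = if (nrow(meta)) meta$resolution_m else NA_real_,
      georef = georef
    ),
    class = "band_raster"
  )
}

#' @export
print.band_raster <- function(x, ...) {
  cat(sprintf(
    "<band_raster %s: %d x %d, %.1f nm, %d%% masked>\n",
    x$band_id, nrow(x$values), ncol(x$values),
    x$central_wavelength_nm, round(100 * mean(x$nodata_mask))
  ))
  invisible(x)
}

#' @export
dim.band_raster <- function(x) dim(x$values)

#' Default georeference metadata
#'
#' A placeholder georeference for synthetic scenes: 10 m pixels anchored at
#' an arbitrary UTM-like origin. Carried through the pipeline and written to
#' raster sidecars; never used in computation.
#'
#' @param origin Numeric length-2, map coordinates of the top-left corner.
#' @param pixel_size Pixel edge length in map units (m).
#' @param crs CRS identifier string.
#' @return Named list.
#' @export
default_georef <- function(origin = c(0, 0), pixel_size = 10, crs = "EPSG:32636") {
  list(origin = origin, pixel_size = pixel_size, crs = crs)
}

#' Tidy a band raster into a long tibble
#'
#' @param x A `band_raster`.
#' @param ... Unused.
#' @return Tibble with columns `row`, `col`, `band_id`, `reflectance`, `masked`.
#' @method tidy band_raster
#' @export
tidy.band_raster <- function(x, ...) {
  tibble(
    row = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
    col = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
    band_id = x$band_id,
    reflectance = as.vector(x$values),
    masked = as.vector(x$nodata_mask)
  )
}
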