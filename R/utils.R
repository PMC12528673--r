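#' Land-suitability class levels
#'
#' The three-way land classification used throughout the pipeline, in the
#' fixed order used for rasters, confusion matrices and reports. The integer
#' raster encoding is `NOT_SUITABLE = 0`, `LOW = 1`, `HIGH = 2`
#' (nodata = 255 in written rasters).
#'
#' @return Character vector `c("NOT_SUITABLE", "LOW", "HIGH")`.
#' @export
land_classes <- function() c("NOT_SUITABLE", "LOW", "HIGH")

# integer raster code for a class label vector
class_to_code <- function(labels) {
  match(labels, land_classes()) - 1L
}

code_to_class <- function(codes) {
  land_classes()[codes + 1L]
}

assert_land_class <- function(x, arg = "land_class") {
  if (!all(x %in% land_classes())) {
    abort(
      paste0(
        "`", arg, "` must be one of ",
        paste(land_classes(), collapse = ", "), "."
      ),
      class = "cropsense_validation_error"
    )
  }
  invisible(x)
}

assert_scalar_number <- function(x, arg, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(
      sprintf("`%s` must be a single finite number in [%s, %s].", arg, min, max),
      class = "cropsense_validation_error"
    )
  }
  invisible(x)
}

assert_count <- function(x, arg, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(
      sprintf("`%s` must be a single integer >= %d.", arg, min),
      class = "cropsense_validation_error"
    )
  }
  invisible(as.integer(x))
}

assert_same_dim <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b))) {
    abort(
      sprintf(
        "%s must share one grid (got %s vs %s).", what,
        paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")
      ),
      class = "cropsense_validation_error"
    )
  }
  invisible(TRUE)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stream-specific child seed from a base seed, keeping it a valid
# 32-bit integer.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) {
    return(NULL)
  }
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
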