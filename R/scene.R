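#' Default per-class reflectance signatures
#'
#' Mean surface reflectance per band for each land-suitability class, chosen
#' to mimic dense irrigated cropland (HIGH), sparse/stressed vegetation (LOW)
#' and dry bare soil (NOT_SUITABLE). The implied standard NDVI values are
#' about 0.84, 0.35 and 0.08 respectively, so the three classes are well
#' separated in index space.
#'
#' @return Named list of named numeric vectors (one per class, one value per
#'   band in [default_band_set()]).
#' @export
#' @examples
#' sig <- default_class_signatures()
#' (sig$HIGH[["B08"]] - sig$HIGH[["B04"]]) / (sig$HIGH[["B08"]] + sig$HIGH[["B04"]])
default_class_signatures <- function() {
  list(
    HIGH = c(B02 = 0.03, B03 = 0.06, B04 = 0.04, B08 = 0.45, B8A = 0.48, B11 = 0.18),
    LOW = c(B02 = 0.06, B03 = 0.09, B04 = 0.12, B08 = 0.25, B8A = 0.27, B11 = 0.22),
    NOT_SUITABLE = c(B02 = 0.12, B03 = 0.16, B04 = 0.22, B08 = 0.26, B8A = 0.27, B11 = 0.45)
  )
}

#' Default blocky class layout
#'
#' Ground-truth label grid with contiguous patches of the three classes,
#' produced by nearest-seed (Voronoi) regions around randomly placed seed
#' points. Contiguous regions give the patch classifier realistic spatial
#' context while every class stays well represented.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param n_seeds Number of Voronoi seed points (at least 3; the first three
#'   are assigned one class each so no class can be absent).
#' @param seed RNG seed.
#' @return Character matrix of class labels.
#' @export
default_class_layout <- function(n_rows, n_cols, n_seeds = 12, seed = 1) {
  n_rows <- assert_count(n_rows, "n_rows")
  n_cols <- assert_count(n_cols, "n_cols")
  n_seeds <- max(3L, assert_count(n_seeds, "n_seeds", min = 3L))
  with_seed(seed, {
    sr <- runif(n_seeds, 1, n_rows)
    sc <- runif(n_seeds, 1, n_cols)
    cls <- c(land_classes(), sample(land_classes(), n_seeds - 3L, replace = TRUE))
    rows <- rep(seq_len(n_rows), times = n_cols)
    cols <- rep(seq_len(n_cols), each = n_rows)
    # squared distance from every pixel to every seed; label = nearest seed's class
    d2 <- outer(rows, sr, `-`)^2 + outer(cols, sc, `-`)^2
    matrix(cls[max.col(-d2, ties.method = "first")], n_rows, n_cols)
  })
}

#' Specify a synthetic multispectral scene
#'
#' Bundles everything needed to simulate a Sentinel-2-like scene with known
#' ground truth: grid size, the per-pixel class layout, per-class band
#' signatures, additive reflectance noise and a seed.
#'
#' @param n_rows,n_cols Grid dimensions (pixels).
#' @param class_layout Character matrix of ground-truth labels covering every
#'   pixel; defaults to [default_class_layout()].
#' @param class_signatures Per-class mean reflectance per band; defaults to
#'   [default_class_signatures()].
#' @param noise_sd Standard deviation of the additive Gaussian reflectance
#'   noise (default 0.01); must be >= 0.
#' @param seed Integer RNG seed.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(n_rows = 64, n_cols = 64,
                       class_layout = NULL,
                       class_signatures = default_class_signatures(),
                       noise_sd = 0.01,
                       seed = 1) {
  n_rows <- assert_count(n_rows, "n_rows")
  n_cols <- assert_count(n_cols, "n_cols")
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  if (is.null(class_layout)) {
    class_layout <- default_class_layout(n_rows, n_cols, seed = derive_seed(seed, 11))
  }
  if (!is.matrix(class_layout) ||
    !identical(dim(class_layout), c(n_rows, n_cols))) {
    abort("`class_layout` must be an n_rows x n_cols matrix covering every pixel.",
      class = "cropsense_validation_error"
    )
  }
  assert_land_class(class_layout, "class_layout")
  missing_cls <- setdiff(unique(as.vector(class_layout)), names(class_signatures))
  if (length(missing_cls)) {
    abort(
      paste0("class_signatures missing for: ", paste(missing_cls, collapse = ", ")),
      class = "cropsense_config_error"
    )
  }
  bands <- names(class_signatures[[1]])
  for (cls in names(class_signatures)) {
    sig <- class_signatures[[cls]]
    if (!identical(sort(names(sig)), sort(bands))) {
      abort("every class signature must cover the same band set.",
        class = "cropsense_config_error"
      )
    }
    if (any(sig < 0 | sig > 1)) {
      abort("signature reflectance must lie in [0, 1].",
        class = "cropsense_config_error"
      )
    }
  }
  unknown <- setdiff(bands, sentinel2_bands()$band_id)
  if (length(unknown)) {
    abort(
      paste0("unknown band in signatures: ", paste(unknown, collapse = ", ")),
      class = "cropsense_config_error"
    )
  }
  structure(
    list(
      n_rows = n_rows, n_cols = n_cols,
      class_layout = class_layout,
      class_signatures = class_signatures,
      bands = bands,
      noise_sd = noise_sd,
      seed = seed
    ),
    class = "scene_spec"
  )
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec %d x %d, %d bands, noise_sd = %g, seed = %s>\n",
    x$n_rows, x$n_cols, length(x$bands), x$noise_sd, x$seed
  ))
  invisible(x)
}

#' Generate a synthetic multispectral scene
#'
#' Draws one reflectance raster per band on a common grid. Each pixel takes
#' its class's mean signature plus i.i.d. Gaussian noise with standard
#' deviation `spec$noise_sd`; values are clipped to the physical \[0, 1\]
#' reflectance range. The ground truth equals the requested class layout, and a
#' fixed (spec, seed) pair reproduces the scene exactly.
#'
#' @param spec A [scene_spec()].
#' @return List with `bands` (named list of [band_raster()] objects) and
#'   `truth` (a [suitability_map()]).
#' @export
#' @examples
#' sc <- generate_scene(scene_spec(16, 16, noise_sd = 0, seed = 1))
#' names(sc$bands)
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) {
    abort("`spec` must be a scene_spec.", class = "cropsense_validation_error")
  }
  georef <- default_georef()
  bands <- with_seed(spec$seed, {
    lapply(setNames(spec$bands, spec$bands), function(b) {
      mu <- matrix(0, spec$n_rows, spec$n_cols)
      for (cls in names(spec$class_signatures)) {
        mu[spec$class_layout == cls] <- spec$class_signatures[[cls]][[b]]
      }
      vals <- mu
      if (spec$noise_sd > 0) {
        vals <- vals + matrix(
          rnorm(spec$n_rows * spec$n_cols, 0, spec$noise_sd),
          spec$n_rows, spec$n_cols
        )
      }
      vals <- pmin(pmax(vals, 0), 1)
      band_raster(b, vals, georef = georef)
    })
  })
  list(
    bands = bands,
    truth = suitability_map(spec$class_layout, georef = georef)
  )
}
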