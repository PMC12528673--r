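#' Construct a land-suitability map
#'
#' A per-pixel classification raster over the three agricultural-preference
#' classes, optionally with per-class probability channels (one per class, in
#' the fixed order NOT_SUITABLE, LOW, HIGH).
#'
#' @param labels Character matrix of class labels from [land_classes()], or an
#'   integer matrix using the raster encoding 0/1/2.
#' @param probabilities Optional rows x cols x 3 array of class probabilities.
#' @param nodata_mask Logical matrix, `TRUE` where no class is defined.
#' @param georef Georeference metadata, see [default_georef()].
#' @return A `suitability_map` object.
#' @export
suitability_map <- function(labels, probabilities = NULL,
                            nodata_mask = NULL, georef = default_georef()) {
  if (is.numeric(labels)) {
    codes <- labels
    if (!all(codes[!is.na(codes)] %in% 0:2)) {
      abort("integer labels must be 0 (NOT_SUITABLE), 1 (LOW) or 2 (HIGH).",
        class = "cropsense_validation_error"
      )
    }
    labels <- matrix(code_to_class(codes), nrow(codes), ncol(codes))
  }
  if (!is.matrix(labels)) {
    abort("`labels` must be a matrix.", class = "cropsense_validation_error")
  }
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, nrow(labels), ncol(labels))
  assert_same_dim(labels, nodata_mask, "labels and nodata_mask")
  assert_land_class(labels[!nodata_mask], "labels")
  if (!is.null(probabilities)) {
    if (!is.array(probabilities) || length(dim(probabilities)) != 3 ||
      dim(probabilities)[3] != 3 ||
      !identical(dim(probabilities)[1:2], dim(labels))) {
      abort("`probabilities` must be a rows x cols x 3 array aligned with `labels`.",
        class = "cropsense_validation_error"
      )
    }
    sums <- apply(probabilities, c(1, 2), sum)
    ok <- nodata_mask | (abs(sums - 1) < 1e-4 & apply(probabilities, c(1, 2), min) >= -1e-9)
    if (!all(ok)) {
      abort("per-pixel probabilities must be nonnegative and sum to 1.",
        class = "cropsense_validation_error"
      )
    }
  }
  structure(
    list(
      labels = labels,
      probabilities = probabilities,
      nodata_mask = nodata_mask,
      georef = georef
    ),
    class = "suitability_map"
  )
}

#' @export
print.suitability_map <- function(x, ...) {
  counts <- table(factor(x$labels[!x$nodata_mask], levels = land_classes()))
  cat(sprintf("<suitability_map %d x %d>\n", nrow(x$labels), ncol(x$labels)))
  print(counts)
  invisible(x)
}

#' @export
dim.suitability_map <- function(x) dim(x$labels)

#' Tidy a suitability map into a long tibble
#'
#' @param x A `suitability_map`.
#' @param ... Unused.
#' @return Tibble with columns `row`, `col`, `class`, `masked`, and, when
#'   probabilities are present, `p_not_suitable`, `p_low`, `p_high`.
#' @method tidy suitability_map
#' @export
tidy.suitability_map <- function(x, ...) {
  out <- tibble(
    row = rep(seq_len(nrow(x$labels)), times = ncol(x$labels)),
    col = rep(seq_len(ncol(x$labels)), each = nrow(x$labels)),
    class = factor(as.vector(x$labels), levels = land_classes()),
    masked = as.vector(x$nodata_mask)
  )
  if (!is.null(x$probabilities)) {
    out$p_not_suitable <- as.vector(x$probabilities[, , 1])
    out$p_low <- as.vector(x$probabilities[, , 2])
    out$p_high <- as.vector(x$probabilities[, , 3])
  }
  out
}

#' Plot a suitability map
#'
#' Renders the class raster with the conventional colours: green for HIGH,
#' red for LOW, black for NOT_SUITABLE.
#'
#' @param object A `suitability_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot suitability_map
#' @export
autoplot.suitability_map <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, !.data$masked)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(NOT_SUITABLE = "black", LOW = "red", HIGH = "forestgreen"),
      drop = FALSE
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Suitability") +
    ggplot2::theme_minimal()
}
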