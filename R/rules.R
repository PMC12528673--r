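#' Default crop-threshold rule set
#'
#' The built-in agronomic thresholds for the five supported crops: admissible
#' ranges (closed intervals) of daily temperature (degrees C), relative
#' humidity (%) and precipitation (mm/day), plus a soil-salinity-tolerance
#' label carried as metadata (no salinity measurement is computed by the
#' pipeline, so it is never evaluated). `required_land_class` is the minimum
#' land-suitability class a pixel must reach before any crop can be
#' recommended there (default HIGH for every crop).
#'
#' @return A `crop_rules` tibble with columns `crop`, `t_min`, `t_max`,
#'   `h_min`, `h_max`, `p_min`, `p_max`, `salinity_tolerance`,
#'   `required_land_class`.
#' @export
#' @examples
#' default_crop_rules()
default_crop_rules <- function() {
  validate_crop_rules(tibble(
    crop = c("Wheat", "Rice", "Maize", "Chickpea", "Sugarcane"),
    t_min = c(10, 20, 18, 15, 21),
    t_max = c(20, 30, 27, 25, 35),
    h_min = c(50, 70, 60, 40, 60),
    h_max = c(70, 90, 80, 60, 80),
    p_min = c(0.1, 3.0, 1.0, 0.0, 2.0),
    p_max = c(1.0, 10.0, 3.0, 1.0, 5.0),
    salinity_tolerance = c("Low", "Medium", "Medium", "High", "Medium"),
    required_land_class = "HIGH"
  ))
}

#' Alternative single-rule rice set
#'
#' Encodes the narrative rice rule (temperature between 22 and 30 degrees C
#' and humidity above 60%) as a named alternative to the systematic default
#' table; precipitation is unconstrained. The humidity bound is encoded as
#' the closed interval \[60, 100\].
#'
#' @return A `crop_rules` tibble with one row.
#' @export
text_rice_rule <- function() {
  validate_crop_rules(tibble(
    crop = "Rice",
    t_min = 22, t_max = 30,
    h_min = 60, h_max = 100,
    p_min = 0, p_max = Inf,
    salinity_tolerance = "Medium",
    required_land_class = "HIGH"
  ))
}

rule_columns <- function() {
  c(
    "crop", "t_min", "t_max", "h_min", "h_max", "p_min", "p_max",
    "salinity_tolerance", "required_land_class"
  )
}

#' Validate a crop rule set
#'
#' Checks column completeness, min <= max for every range, unique crop
#' names, known salinity labels and land classes.
#'
#' @param rules A data frame of crop thresholds.
#' @return The validated `crop_rules` tibble.
#' @export
validate_crop_rules <- function(rules) {
  rules <- as_tibble(rules)
  missing <- setdiff(rule_columns(), names(rules))
  if (length(missing)) {
    abort(
      paste0("rule set missing columns: ", paste(missing, collapse = ", ")),
      class = "cropsense_config_error"
    )
  }
  unknown <- setdiff(names(rules), rule_columns())
  if (length(unknown)) {
    abort(
      paste0("unknown rule field(s): ", paste(unknown, collapse = ", ")),
      class = "cropsense_config_error"
    )
  }
  if (anyDuplicated(rules$crop)) {
    abort(
      paste0(
        "duplicate crop row(s): ",
        paste(unique(rules$crop[duplicated(rules$crop)]), collapse = ", ")
      ),
      class = "cropsense_config_error"
    )
  }
  for (pair in list(c("t_min", "t_max"), c("h_min", "h_max"), c("p_min", "p_max"))) {
    bad <- which(rules[[pair[1]]] > rules[[pair[2]]])
    if (length(bad)) {
      abort(
        sprintf(
          "row %s (%s): %s > %s.", bad[1], rules$crop[bad[1]], pair[1], pair[2]
        ),
        class = "cropsense_config_error"
      )
    }
  }
  if (!all(rules$salinity_tolerance %in% c("Low", "Medium", "High"))) {
    abort("salinity_tolerance must be Low, Medium or High.",
      class = "cropsense_config_error"
    )
  }
  assert_land_class(rules$required_land_class, "required_land_class")
  structure(rules, class = c("crop_rules", class(tibble())))
}

#' Load a crop rule set from YAML or JSON
#'
#' The file holds a list of crop records with the fields of
#' [default_crop_rules()]. Missing `required_land_class` defaults to HIGH;
#' a missing precipitation ceiling defaults to unbounded.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` rule file.
#' @return A `crop_rules` tibble.
#' @export
load_crop_rules <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("rule file not found: ", path), class = "cropsense_config_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$crops)) raw <- raw$crops
  rows <- purrr::map_dfr(raw, function(r) {
    tibble(
      crop = r$crop,
      t_min = as.numeric(r$t_min), t_max = as.numeric(r$t_max),
      h_min = as.numeric(r$h_min), h_max = as.numeric(r$h_max),
      p_min = as.numeric(r$p_min %||% 0),
      p_max = as.numeric(r$p_max %||% Inf),
      salinity_tolerance = r$salinity_tolerance %||% "Medium",
      required_land_class = r$required_land_class %||% "HIGH"
    )
  })
  validate_crop_rules(rows)
}

#' Save a crop rule set to YAML or JSON
#'
#' @param rules A `crop_rules` tibble.
#' @param path Destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_crop_rules <- function(rules, path) {
  rules <- validate_crop_rules(rules)
  recs <- purrr::pmap(rules, function(...) list(...))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(crops = recs), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(list(crops = recs), path)
  }
  invisible(path)
}

land_class_rank <- function(x) match(x, land_classes())

#' Match crops to a weather reading
#'
#' Returns every crop whose temperature, humidity and precipitation ranges
#' (closed intervals, boundary-inclusive) all contain the reading, in
#' rule-set order. An empty result is a valid outcome.
#'
#' @param reading Named list or one-row data frame with `temperature`,
#'   `humidity`, `precipitation`.
#' @param rules A `crop_rules` tibble.
#' @return Character vector of matching crop names.
#' @export
#' @examples
#' match_crops(list(temperature = 25, humidity = 85, precipitation = 4))
match_crops <- function(reading, rules = default_crop_rules()) {
  if (!inherits(rules, "crop_rules")) rules <- validate_crop_rules(rules)
  reading <- as.list(reading)
  for (f in c("temperature", "humidity", "precipitation")) {
    if (is.null(reading[[f]])) {
      abort(paste0("reading missing `", f, "`."), class = "cropsense_validation_error")
    }
  }
  assert_scalar_number(reading$temperature, "temperature")
  assert_scalar_number(reading$humidity, "humidity", 0, 100)
  assert_scalar_number(reading$precipitation, "precipitation", min = 0)
  hit <- reading$temperature >= rules$t_min & reading$temperature <= rules$t_max &
    reading$humidity >= rules$h_min & reading$humidity <= rules$h_max &
    reading$precipitation >= rules$p_min & reading$precipitation <= rules$p_max
  rules$crop[hit]
}

#' Recommend crops for one reading and land class
#'
#' Combines the temporal (weather) and spatial (land-suitability) conditions:
#' a crop is recommended only when the reading falls inside all three of its
#' ranges and the land class reaches the crop's required class. When nothing
#' qualifies the verdict is the literal `"Unsuitable conditions"`.
#'
#' @param reading Named list with `temperature`, `humidity`, `precipitation`
#'   (and optionally `date`, `pressure` — carried, unused).
#' @param land_class One of [land_classes()].
#' @param rules A `crop_rules` tibble.
#' @param rank If `TRUE`, order matched crops by the normalized distance of
#'   the reading to each crop's range midpoints (closest first) instead of
#'   rule-set order.
#' @return A `recommendation` list with `matched_crops`, `verdict`,
#'   `land_class_used`, `reading_used`, `rule_set_id`.
#' @export
#' @examples
#' recommend(list(temperature = 25, humidity = 85, precipitation = 4), "HIGH")
recommend <- function(reading, land_class, rules = default_crop_rules(),
                      rank = FALSE) {
  if (length(land_class) != 1 || !land_class %in% land_classes()) {
    abort(
      paste0(
        "`land_class` must be one of ", paste(land_classes(), collapse = ", "), "."
      ),
      class = "cropsense_validation_error"
    )
  }
  if (!inherits(rules, "crop_rules")) rules <- validate_crop_rules(rules)
  eligible <- rules[land_class_rank(land_class) >=
    land_class_rank(rules$required_land_class), , drop = FALSE]
  matched <- if (nrow(eligible)) match_crops(reading, eligible) else character(0)
  if (rank && length(matched) > 1) {
    sub <- eligible[match(matched, eligible$crop), ]
    dist <- sqrt(
      ((as.numeric(reading$temperature) - (sub$t_min + sub$t_max) / 2) /
        pmax(sub$t_max - sub$t_min, 1e-9))^2 +
        ((as.numeric(reading$humidity) - (sub$h_min + sub$h_max) / 2) /
          pmax(sub$h_max - sub$h_min, 1e-9))^2 +
        ((as.numeric(reading$precipitation) - (sub$p_min + sub$p_max) / 2) /
          pmax(sub$p_max - sub$p_min, 1e-9))^2
    )
    matched <- matched[order(dist)]
  }
  structure(
    list(
      matched_crops = matched,
      verdict = if (length(matched)) matched else "Unsuitable conditions",
      land_class_used = land_class,
      reading_used = as.list(reading),
      rule_set_id = paste(sort(rules$crop), collapse = "+")
    ),
    class = "recommendation"
  )
}

#' @export
print.recommendation <- function(x, ...) {
  v <- if (identical(x$verdict, "Unsuitable conditions")) {
    x$verdict
  } else {
    paste(x$verdict, collapse = ", ")
  }
  cat(sprintf("<recommendation [%s]: %s>\n", x$land_class_used, v))
  invisible(x)
}

#' Recommend crops over a forecast horizon
#'
#' Applies [recommend()] to every day of a forecast series at one land
#' class, returning a dated tibble plus per-crop match counts over the
#' horizon.
#'
#' @param forecast A weather/forecast series tibble (columns `time`,
#'   `temperature_2m`, `rel_humidity_2m`, `total_precip`, `pressure`).
#' @param land_class One of [land_classes()].
#' @param rules A `crop_rules` tibble.
#' @return Tibble (class `recommendation_series`) with columns `time`,
#'   `land_class`, `matched_crops` (list-column), `verdict` (collapsed
#'   string); per-crop totals in the `summary` attribute.
#' @export
recommend_series <- function(forecast, land_class, rules = default_crop_rules()) {
  if (!nrow(forecast)) {
    abort("forecast must be nonempty.", class = "cropsense_validation_error")
  }
  if (!inherits(rules, "crop_rules")) rules <- validate_crop_rules(rules)
  recs <- purrr::pmap(
    list(
      forecast$time, forecast$temperature_2m,
      forecast$rel_humidity_2m, forecast$total_precip
    ),
    function(time, t, h, p) {
      recommend(
        list(temperature = t, humidity = h, precipitation = p, date = time),
        land_class, rules
      )
    }
  )
  matched <- purrr::map(recs, "matched_crops")
  out <- tibble(
    time = forecast$time,
    land_class = land_class,
    matched_crops = matched,
    verdict = purrr::map_chr(recs, function(r) {
      if (length(r$matched_crops)) paste(r$matched_crops, collapse = "; ") else "Unsuitable conditions"
    })
  )
  counts <- table(factor(unlist(matched), levels = rules$crop))
  structure(out,
    summary = as_tibble(as.data.frame(counts, stringsAsFactors = FALSE)) |>
      setNames(c("crop", "days_matched")),
    class = c("recommendation_series", class(tibble()))
  )
}
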