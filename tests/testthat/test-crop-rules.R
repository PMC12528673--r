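test_that("the default rule set holds the five crops with valid ranges", {
  rules <- default_crop_rules()
  expect_identical(nrow(rules), 5L)
  expect_identical(
    rules$crop,
    c("Wheat", "Rice", "Maize", "Chickpea", "Sugarcane")
  )
  expect_true(all(rules$t_min <= rules$t_max))
  expect_true(all(rules$required_land_class == "HIGH"))
})

test_that("malformed rule sets are rejected with the offending row named", {
  bad <- default_crop_rules()
  bad$t_min[1] <- 30
  expect_error(validate_crop_rules(bad), "Wheat", class = "cropsense_config_error")
  dup <- dplyr::bind_rows(default_crop_rules(), default_crop_rules()[1, ])
  expect_error(validate_crop_rules(dup), "Wheat", class = "cropsense_config_error")
  extra <- default_crop_rules()
  extra$bogus <- 1
  expect_error(validate_crop_rules(extra), "bogus", class = "cropsense_config_error")
})

test_that("rule sets round-trip through YAML and JSON exactly", {
  rules <- default_crop_rules()
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    save_crop_rules(rules, path)
    back <- load_crop_rules(path)
    expect_equal(as.data.frame(back), as.data.frame(rules))
  }
})

test_that("readings match exactly the crops whose closed intervals contain them", {
  expect_identical(
    match_crops(list(temperature = 25, humidity = 85, precipitation = 4)),
    "Rice"
  )
  # the winter station reading matches nothing
  expect_identical(
    length(match_crops(list(temperature = 15.34, humidity = 80, precipitation = 0.07))),
    0L
  )
  expect_identical(
    match_crops(list(temperature = 15, humidity = 60, precipitation = 0.5)),
    c("Wheat", "Chickpea")
  )
})

test_that("interval boundaries are inclusive on both ends", {
  rules <- default_crop_rules()
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    at_min <- list(temperature = r$t_min, humidity = r$h_min, precipitation = r$p_min)
    at_max <- list(temperature = r$t_max, humidity = r$h_max, precipitation = r$p_max)
    expect_true(r$crop %in% match_crops(at_min, rules))
    expect_true(r$crop %in% match_crops(at_max, rules))
  }
})

test_that("match_crops agrees with the brute-force oracle on random readings", {
  rules <- default_crop_rules()
  set.seed(99)
  readings <- purrr::map(seq_len(10000), function(i) {
    list(
      temperature = runif(1, -5, 45),
      humidity = runif(1, 0, 100),
      precipitation = runif(1, 0, 12)
    )
  })
  got <- purrr::map(readings, match_crops, rules = rules)
  want <- purrr::map(readings, brute_force_match, rules = rules)
  expect_identical(got, want)
  # and every crop matched at least once over the sweep
  expect_identical(sort(unique(unlist(want))), sort(rules$crop))
})

test_that("the land-class gate blocks recommendations below the required class", {
  rice_day <- list(temperature = 25, humidity = 85, precipitation = 4)
  expect_identical(
    recommend(rice_day, "NOT_SUITABLE")$verdict,
    "Unsuitable conditions"
  )
  expect_identical(recommend(rice_day, "LOW")$verdict, "Unsuitable conditions")
  expect_identical(recommend(rice_day, "HIGH")$verdict, "Rice")
  expect_error(recommend(rice_day, "MEDIUM"), class = "cropsense_validation_error")
  # tightening the class never adds crops
  wheat_day <- list(temperature = 15, humidity = 55, precipitation = 0.5)
  high <- recommend(wheat_day, "HIGH")$matched_crops
  expect_identical(high, c("Wheat", "Chickpea"))
  low <- recommend(wheat_day, "LOW")$matched_crops
  expect_true(all(low %in% high))
})

test_that("verdict is 'Unsuitable conditions' exactly when nothing matches", {
  set.seed(123)
  for (i in 1:200) {
    reading <- list(
      temperature = runif(1, -5, 45),
      humidity = runif(1, 0, 100),
      precipitation = runif(1, 0, 12)
    )
    rec <- recommend(reading, "HIGH")
    if (length(rec$matched_crops)) {
      expect_identical(rec$verdict, rec$matched_crops)
    } else {
      expect_identical(rec$verdict, "Unsuitable conditions")
    }
  }
})

test_that("ranked recommendations order matches by distance to range midpoints", {
  # dead-centre of Wheat's ranges, inside Chickpea's but off-centre
  reading <- list(temperature = 15, humidity = 60, precipitation = 0.55)
  ranked <- recommend(reading, "HIGH", rank = TRUE)
  expect_identical(ranked$matched_crops[1], "Wheat")
})

test_that("the alternative narrative rice rule is available", {
  rules <- text_rice_rule()
  expect_identical(rules$crop, "Rice")
  expect_identical(
    match_crops(list(temperature = 23, humidity = 65, precipitation = 0), rules),
    "Rice"
  )
  # outside Table-7 rice humidity but inside the narrative rule
  expect_identical(
    length(match_crops(
      list(temperature = 23, humidity = 65, precipitation = 0),
      default_crop_rules()
    )),
    0L
  )
})

test_that("recommend_series maps each forecast day and counts matches", {
  fc <- tibble::tibble(
    time = as.Date("2024-07-01") + 0:10,
    temperature_2m = c(rep(28, 6), rep(27.5, 5)),
    rel_humidity_2m = rep(c(75, 80, 85), length.out = 11),
    total_precip = rep(4, 11),
    pressure = rep(100.6, 11)
  )
  recs <- recommend_series(fc, "HIGH")
  expect_identical(nrow(recs), 11L)
  expect_true(all(purrr::map_lgl(recs$matched_crops, ~"Rice" %in% .x)))
  summary <- attr(recs, "summary")
  expect_identical(summary$days_matched[summary$crop == "Rice"], 11L)
  # identical readings give identical recommendations
  flat <- dplyr::mutate(fc,
    temperature_2m = 25, rel_humidity_2m = 85,
    total_precip = 4
  )
  flat_recs <- recommend_series(flat, "HIGH")
  expect_identical(unique(flat_recs$verdict), "Rice")
  expect_error(recommend_series(fc[0, ], "HIGH"), class = "cropsense_validation_error")
})
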