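# Shared fixtures: everything is generated in code, nothing read from disk.

# a small noiseless scene with all three classes present
tiny_scene <- function(n = 16, noise_sd = 0, seed = 1) {
  generate_scene(scene_spec(n, n, noise_sd = noise_sd, seed = seed))
}

tiny_stack <- function(scene = tiny_scene()) {
  compute_index_stack(scene$bands)
}

# a light classifier configuration for fast structural tests
fast_classifier_config <- function(...) {
  args <- utils::modifyList(
    list(
      conv_filters = c(8, 12, 16), dense_units = c(16, 8),
      max_epochs = 3, max_train_samples = 300
    ),
    list(...)
  )
  do.call(classifier_config, args)
}

# a light forecaster configuration for fast structural tests
fast_forecaster_config <- function(...) {
  args <- utils::modifyList(list(lstm_units = 8, epochs = 3), list(...))
  do.call(forecaster_config, args)
}

# three-year seasonal weather plus a 30-day verification tail
seasonal_weather <- function(seed, n_extra = 30, start = "2024-01-01") {
  generate_weather(weather_sim_params(
    start_date = start, n_days = 3 * 365 + n_extra, seed = seed
  ))
}

# brute-force one-vs-rest reading match, independent of match_crops()
brute_force_match <- function(reading, rules) {
  hits <- character(0)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    ok <- reading$temperature >= r$t_min && reading$temperature <= r$t_max &&
      reading$humidity >= r$h_min && reading$humidity <= r$h_max &&
      reading$precipitation >= r$p_min && reading$precipitation <= r$p_max
    if (ok) hits <- c(hits, r$crop)
  }
  hits
}

# independent confusion-matrix tally by explicit double loop
brute_force_confusion <- function(truth, predicted) {
  classes <- land_classes()
  out <- matrix(0L, 3, 3, dimnames = list(truth = classes, predicted = classes))
  for (i in seq_along(truth)) {
    out[truth[i], predicted[i]] <- out[truth[i], predicted[i]] + 1L
  }
  out
}

# central-difference numerical gradient of f at x (array-shaped)
numerical_gradient <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x
    xp[i] <- x[i] + eps
    xm <- x
    xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
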