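test_that("window counts equal n - L for every admissible pair", {
  base <- generate_weather(weather_sim_params(n_days = 30, seed = 1))
  for (n in c(5L, 12L, 30L)) {
    series <- base[seq_len(n), ]
    for (L in seq_len(n - 1)) {
      wd <- make_windows(series, L)
      expect_identical(dim(wd$inputs)[1], n - L)
      expect_identical(nrow(wd$targets), n - L)
    }
  }
})

test_that("window boundaries and chronology are exact", {
  w <- generate_weather(weather_sim_params(n_days = 10, seed = 2))
  wd <- make_windows(w, 7)
  expect_identical(dim(wd$inputs), c(3L, 7L, 4L))
  # sample 1 inputs are days 1..7, target day 8
  expect_equal(wd$inputs[1, , 1], w$temperature_2m[1:7])
  expect_equal(unname(wd$targets[1, 1]), w$temperature_2m[8])
  expect_identical(wd$target_times[1], w$time[8])
  # n = L + 1 gives exactly one sample; n = L errors
  expect_identical(dim(make_windows(w[1:8, ], 7)$inputs)[1], 1L)
  expect_error(make_windows(w[1:7, ], 7), class = "cropsense_validation_error")
})

test_that("gapped series are rejected with the gap named", {
  w <- generate_weather(weather_sim_params(n_days = 10, seed = 3))
  gapped <- w[-4, ]
  expect_error(make_windows(gapped, 3), "gap", class = "cropsense_validation_error")
})

test_that("feature scaling round-trips and flags constants", {
  set.seed(4)
  M <- cbind(
    temperature_2m = rnorm(50, 20, 5), rel_humidity_2m = runif(50, 30, 90),
    total_precip = rexp(50), pressure = rep(100.8, 50)
  )
  expect_warning(s <- cropsense:::fit_feature_scaler(M), "pressure")
  scaled <- cropsense:::scale_features(M, s)
  expect_true(all(scaled[, 1:3] >= 0 & scaled[, 1:3] <= 1))
  back <- cropsense:::unscale_features(scaled, s)
  expect_equal(back, M, tolerance = 1e-12)
})

test_that("LSTM gradients match finite differences", {
  set.seed(5)
  B <- 3
  L <- 4
  U <- 5
  X <- array(rnorm(B * L * 4), c(B, L, 4))
  Tg <- matrix(runif(B * 4), B, 4)
  params <- cropsense:::init_lstm_params(4, U, 4)
  loss_of <- function(p) {
    mean((cropsense:::lstm_forward(p, X, U)$y - Tg)^2)
  }
  fw <- cropsense:::lstm_forward(params, X, U)
  gr <- cropsense:::lstm_backward(params, fw, Tg, U)
  for (nm in names(params)) {
    num <- numerical_gradient(function(v) {
      p <- params
      p[[nm]] <- v
      loss_of(p)
    }, params[[nm]])
    expect_lt(max(abs(num - gr[[nm]])), 1e-7)
  }
})

test_that("training is reproducible and history respects the epoch budget", {
  w <- generate_weather(weather_sim_params(n_days = 120, seed = 6))
  cfg <- fast_forecaster_config(seed = 3)
  m1 <- train_forecaster(w, cfg)
  m2 <- train_forecaster(w, cfg)
  expect_identical(m1$params, m2$params)
  win <- w[(nrow(w) - 6):nrow(w), ]
  expect_identical(forecast_weather(m1, win, 10), forecast_weather(m2, win, 10))
  expect_lte(nrow(m1$history), cfg$epochs)
  expect_lte(
    m1$history$loss[nrow(m1$history)],
    m1$history$loss[1]
  )
})

test_that("a pure weekly cycle is learned to near-zero loss", {
  base <- tibble::tibble(
    time = as.Date("2024-01-01") + 0:349,
    temperature_2m = rep(c(10, 12, 15, 18, 16, 13, 11), 50),
    rel_humidity_2m = rep(c(60, 55, 50, 45, 48, 52, 58), 50),
    total_precip = rep(c(0, 0, 1, 0, 0, 2, 0), 50),
    pressure = rep(c(100.5, 100.6, 100.7, 100.8, 100.7, 100.6, 100.5), 50)
  )
  m <- train_forecaster(base, forecaster_config(
    lstm_units = 16, epochs = 60,
    early_stopping_patience = 20, seed = 1
  ))
  expect_lt(min(m$history$val_loss, na.rm = TRUE), 5e-3)
  # the forecast continues the cycle closely
  win <- base[(nrow(base) - 6):nrow(base), ]
  fc <- forecast_weather(m, win, 14)
  truth <- rep(c(10, 12, 15, 18, 16, 13, 11), 2)
  expect_lt(regression_errors(truth, fc$temperature_2m)$rmse, 1)
})

test_that("forecast horizons, dates and physical bounds hold", {
  w <- generate_weather(weather_sim_params(n_days = 150, seed = 8))
  m <- train_forecaster(w, fast_forecaster_config(seed = 2))
  win <- w[(nrow(w) - 6):nrow(w), ]
  empty <- forecast_weather(m, win, 0)
  expect_identical(nrow(empty), 0L)
  fc <- forecast_weather(m, win, 11)
  expect_identical(nrow(fc), 11L)
  expect_identical(fc$time, max(w$time) + 1:11)
  expect_true(all(fc$rel_humidity_2m >= 0 & fc$rel_humidity_2m <= 100))
  expect_true(all(fc$total_precip >= 0))
  expect_error(forecast_weather(m, w[1:3, ], 5), class = "cropsense_validation_error")
})

test_that("the persistence baseline repeats the last observation verbatim", {
  win <- tibble::tibble(
    time = as.Date("2023-12-26") + 0:6,
    temperature_2m = c(14, 14.5, 15, 15.2, 15.1, 15.3, 15.34),
    rel_humidity_2m = c(70, 72, 75, 78, 79, 79.5, 80),
    total_precip = c(0, 0, 0.1, 0, 0.05, 0, 0.07),
    pressure = c(100.8, 100.82, 100.85, 100.86, 100.86, 100.87, 100.87)
  )
  fc <- persistence_baseline(win, 3)
  expect_identical(nrow(fc), 3L)
  expect_true(all(fc$temperature_2m == 15.34))
  expect_true(all(fc$rel_humidity_2m == 80))
  expect_true(all(fc$total_precip == 0.07))
  expect_true(all(fc$pressure == 100.87))
  expect_identical(nrow(persistence_baseline(win, 0)), 0L)
  expect_error(persistence_baseline(win[0, ], 3), class = "cropsense_validation_error")
  # exact on constants
  const <- win
  const[, -1] <- lapply(const[, -1], function(x) rep(20, 7))
  fc2 <- persistence_baseline(const, 5)
  expect_equal(regression_errors(rep(20, 5), fc2$temperature_2m)$rmse, 0)
})

test_that("the forecaster beats persistence on a noiseless seasonal cycle", {
  w <- generate_weather(weather_sim_params(
    start_date = "2021-01-01", n_days = 3 * 365 + 30, seed = 5,
    temp_noise_sd = 0, humidity_noise_sd = 0, precip_wet_prob = 0,
    pressure_noise_sd = 0
  ))
  train <- w[1:(3 * 365), ]
  future <- w[(3 * 365 + 1):(3 * 365 + 30), ]
  suppressWarnings(
    m <- train_forecaster(train, forecaster_config(seed = 5))
  )
  win <- train[(nrow(train) - 6):nrow(train), ]
  fc <- forecast_weather(m, win, 30)
  pb <- persistence_baseline(win, 30)
  expect_lte(
    regression_errors(future$temperature_2m, fc$temperature_2m)$rmse,
    regression_errors(future$temperature_2m, pb$temperature_2m)$rmse
  )
})
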