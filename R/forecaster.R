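#' Configuration for the sliding-window weather forecaster
#'
#' A recurrent network with LSTM units reads a window of `window_length`
#' consecutive days of scaled weather features (temperature, humidity,
#' precipitation, pressure) and predicts the next day's scaled feature
#' vector through a sigmoid output layer. Multi-day forecasts roll the
#' one-step model forward, feeding each prediction back into the window.
#'
#' @param window_length Days per input window (default 7; 5-7 typical).
#' @param lstm_units Hidden state width (default 64).
#' @param dropout_rate Dropout on the final hidden state during training.
#' @param batch_size Windows per optimizer step (default 32).
#' @param epochs Maximum training epochs (default 50).
#' @param learning_rate Adam step size.
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping.
#' @param validation_split Fraction of days (chronological tail) held out.
#' @param horizon Default forecast horizon in days.
#' @param mos_correction Apply a per-variable linear output calibration
#'   (model output statistics) fitted on the validation predictions; reduces
#'   the systematic level bias that otherwise accumulates during iterative
#'   roll-out (default `TRUE`).
#' @param seed Integer RNG seed.
#' @return A `forecaster_config` object.
#' @export
forecaster_config <- function(window_length = 7,
                              lstm_units = 64,
                              dropout_rate = 0.2,
                              batch_size = 32,
                              epochs = 50,
                              learning_rate = 0.005,
                              early_stopping_patience = 12,
                              validation_split = 0.2,
                              horizon = 30,
                              mos_correction = TRUE,
                              seed = 1) {
  window_length <- assert_count(window_length, "window_length")
  assert_scalar_number(dropout_rate, "dropout_rate", 0, 1 - 1e-9)
  assert_scalar_number(validation_split, "validation_split", 0.05, 0.5)
  if (horizon < 0) {
    abort("`horizon` must be >= 0.", class = "cropsense_validation_error")
  }
  structure(
    list(
      window_length = window_length,
      lstm_units = assert_count(lstm_units, "lstm_units"),
      dropout_rate = dropout_rate,
      batch_size = assert_count(batch_size, "batch_size"),
      epochs = assert_count(epochs, "epochs"),
      learning_rate = learning_rate,
      early_stopping_patience = assert_count(early_stopping_patience,
        "early_stopping_patience",
        min = 1L
      ),
      validation_split = validation_split,
      horizon = as.integer(horizon),
      mos_correction = isTRUE(mos_correction),
      seed = seed
    ),
    class = "forecaster_config"
  )
}

forecast_features <- function() {
  c("temperature_2m", "rel_humidity_2m", "total_precip", "pressure")
}

#' Build a supervised sliding-window dataset
#'
#' Sample `i` uses days `i ... i+L-1` as input and day `i+L` as target, so a
#' series of `n` days yields exactly `n - L` samples. Gaps in the daily
#' timestamps are rejected, never imputed.
#'
#' @param series A weather series tibble (see [generate_weather()]).
#' @param window_length Window length L in days.
#' @return A `windowed_dataset`: list with `inputs` (N x L x 4 array),
#'   `targets` (N x 4 matrix), `target_times` (dates of the predicted days).
#' @export
#' @examples
#' w <- generate_weather(weather_sim_params(n_days = 10))
#' dim(make_windows(w, 7)$inputs)
make_windows <- function(series, window_length) {
  window_length <- assert_count(window_length, "window_length")
  series <- validate_weather_series(series)
  n <- nrow(series)
  if (n <= window_length) {
    abort(
      sprintf(
        "series length (%d) must exceed window_length (%d).", n, window_length
      ),
      class = "cropsense_validation_error"
    )
  }
  M <- as.matrix(series[forecast_features()])
  wm <- window_matrix(M, window_length)
  structure(
    c(wm, list(target_times = as.Date(series$time)[(window_length + 1):n])),
    class = "windowed_dataset"
  )
}

# windowing on a plain feature matrix (used on scaled features internally)
window_matrix <- function(M, L) {
  n <- nrow(M)
  N <- n - L
  inputs <- array(NA_real_, c(N, L, ncol(M)))
  for (t in seq_len(L)) {
    inputs[, t, ] <- M[t:(t + N - 1), , drop = FALSE]
  }
  list(inputs = inputs, targets = M[(L + 1):n, , drop = FALSE])
}

# ---- feature scaling -------------------------------------------------------

fit_feature_scaler <- function(M) {
  mins <- apply(M, 2, min)
  maxs <- apply(M, 2, max)
  degenerate <- maxs == mins
  if (any(degenerate)) {
    warn(
      paste0(
        "constant feature(s) carried through unscaled: ",
        paste(colnames(M)[degenerate], collapse = ", ")
      )
    )
  }
  structure(
    list(min = mins, max = maxs, degenerate = degenerate),
    class = "feature_scaler"
  )
}

scale_features <- function(M, scaler) {
  rng <- scaler$max - scaler$min
  rng[scaler$degenerate] <- 1
  sweep(sweep(M, 2, scaler$min), 2, rng, `/`)
}

unscale_features <- function(M, scaler) {
  rng <- scaler$max - scaler$min
  rng[scaler$degenerate] <- 0 # constants map back to their single value
  sweep(sweep(M, 2, rng, `*`), 2, scaler$min, `+`)
}

# ---- LSTM core -------------------------------------------------------------

init_lstm_params <- function(n_in, units, n_out) {
  p <- list(
    Wx = glorot_uniform(n_in, 4 * units, c(n_in, 4 * units)),
    Wh = glorot_uniform(units, 4 * units, c(units, 4 * units)),
    b = rep(0, 4 * units),
    Wy = glorot_uniform(units, n_out, c(units, n_out)),
    by = rep(0, n_out)
  )
  p$b[(units + 1):(2 * units)] <- 1 # forget-gate bias
  p
}

# forward a batch of windows; X is (B, L, D). Returns caches for BPTT.
lstm_forward <- function(params, X, units, dropout_rate = 0, train = FALSE) {
  B <- dim(X)[1]
  L <- dim(X)[2]
  h <- matrix(0, B, units)
  cst <- matrix(0, B, units)
  steps <- vector("list", L)
  ui <- seq_len(units)
  for (t in seq_len(L)) {
    xt <- X[, t, , drop = TRUE]
    if (is.null(dim(xt))) xt <- matrix(xt, B)
    z <- xt %*% params$Wx + h %*% params$Wh
    z <- sweep(z, 2, params$b, `+`)
    i <- sigmoid(z[, ui, drop = FALSE])
    f <- sigmoid(z[, ui + units, drop = FALSE])
    g <- tanh(z[, ui + 2 * units, drop = FALSE])
    o <- sigmoid(z[, ui + 3 * units, drop = FALSE])
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h_prev <- h
    h <- o * tc
    steps[[t]] <- list(
      x = xt, i = i, f = f, g = g, o = o,
      c_prev = c_prev, c = cst, tc = tc, h_prev = h_prev
    )
  }
  drop_cache <- dropout_forward(h, dropout_rate, train)
  pre <- sweep(drop_cache$out %*% params$Wy, 2, params$by, `+`)
  y <- sigmoid(pre)
  list(y = y, h = h, steps = steps, drop = drop_cache, L = L, B = B)
}

# gradient of mean-squared error on the sigmoid outputs
lstm_backward <- function(params, cache, target, units) {
  B <- cache$B
  y <- cache$y
  dy <- 2 * (y - target) / length(y)
  dpre <- dy * y * (1 - y)
  hd <- cache$drop$out
  grads <- list(
    Wx = params$Wx * 0, Wh = params$Wh * 0, b = params$b * 0,
    Wy = t(hd) %*% dpre, by = colSums(dpre)
  )
  dh <- dropout_backward(dpre %*% t(params$Wy), cache$drop)
  dc <- matrix(0, B, units)
  for (t in rev(seq_len(cache$L))) {
    s <- cache$steps[[t]]
    do <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dzi <- di * s$i * (1 - s$i)
    dzf <- df * s$f * (1 - s$f)
    dzg <- dg * (1 - s$g^2)
    dzo <- do * s$o * (1 - s$o)
    dz <- cbind(dzi, dzf, dzg, dzo)
    grads$Wx <- grads$Wx + t(s$x) %*% dz
    grads$Wh <- grads$Wh + t(s$h_prev) %*% dz
    grads$b <- grads$b + colSums(dz)
    dh <- dz %*% t(params$Wh)
    dc <- dc * s$f
  }
  grads
}

#' Train the weather forecaster
#'
#' Fits the min-max feature scaler on the chronological training span only
#' (the last `validation_split` of days is held out), builds one-day-ahead
#' sliding windows, and trains the LSTM with Adam on mean squared error over
#' scaled targets, with early stopping on validation loss.
#'
#' @param series A weather series tibble.
#' @param config A [forecaster_config()].
#' @return A `weather_forecaster` with elements `params`, `scaler`, `config`,
#'   `history` (per-epoch losses), `train_tail` (the last window of the
#'   training data, the default context for [forecast()]).
#' @export
train_forecaster <- function(series, config = forecaster_config()) {
  series <- validate_weather_series(series)
  L <- config$window_length
  n <- nrow(series)
  n_train <- floor(n * (1 - config$validation_split))
  if (n_train <= L + 1) {
    abort("series too short for the configured window and split.",
      class = "cropsense_validation_error"
    )
  }
  M <- as.matrix(series[forecast_features()])
  scaler <- fit_feature_scaler(M[seq_len(n_train), , drop = FALSE])
  Ms <- scale_features(M, scaler)
  wd <- window_matrix(Ms, L)
  is_train <- seq_len(nrow(wd$targets)) + L <= n_train
  tr_idx <- which(is_train)
  va_idx <- which(!is_train)
  units <- config$lstm_units

  with_seed(config$seed, {
    params <- init_lstm_params(4, units, 4)
    opt <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    history <- list()
    wait <- 0L
    # learning-rate reduction on plateau: halve after 4 stale epochs, floored
    # at lr/25 — the fine-convergence phase matters for roll-out stability
    lr <- config$learning_rate
    min_lr <- config$learning_rate / 25
    stale <- 0L

    eval_loss <- function(idx) {
      if (!length(idx)) {
        return(NA_real_)
      }
      total <- 0
      for (chunk in split(idx, ceiling(seq_along(idx) / 512))) {
        fw <- lstm_forward(params, wd$inputs[chunk, , , drop = FALSE], units)
        total <- total + mean((fw$y - wd$targets[chunk, , drop = FALSE])^2) *
          length(chunk)
      }
      total / length(idx)
    }

    for (epoch in seq_len(config$epochs)) {
      order <- sample(tr_idx)
      epoch_loss <- 0
      for (b in split(order, ceiling(seq_along(order) / config$batch_size))) {
        Xb <- wd$inputs[b, , , drop = FALSE]
        Tb <- wd$targets[b, , drop = FALSE]
        fw <- lstm_forward(params, Xb, units, config$dropout_rate, train = TRUE)
        loss <- mean((fw$y - Tb)^2)
        epoch_loss <- epoch_loss + loss * length(b)
        grads <- lstm_backward(params, fw, Tb, units)
        step <- adam_step(params, grads, opt, lr = lr)
        params <- step$params
        opt <- step$state
      }
      epoch_loss <- epoch_loss / length(order)
      val <- eval_loss(va_idx)
      history[[epoch]] <- tibble(
        epoch = epoch, loss = epoch_loss, val_loss = val, lr = lr
      )
      monitor <- if (is.na(val)) epoch_loss else val
      if (monitor < best$loss - 1e-9) {
        best <- list(loss = monitor, params = params, epoch = epoch)
        wait <- 0L
        stale <- 0L
      } else {
        wait <- wait + 1L
        stale <- stale + 1L
        if (stale >= 4L && lr > min_lr) {
          lr <- max(lr / 2, min_lr)
          stale <- 0L
        }
        if (wait >= config$early_stopping_patience) break
      }
    }
    params <- best$params

    # Model-output-statistics calibration: per-variable linear map from the
    # one-step validation predictions to the observed scaled values. Applied
    # at every roll-out step; corrects the small level bias a recursive
    # forecast otherwise locks onto.
    mos <- rbind(intercept = rep(0, 4), slope = rep(1, 4))
    if (config$mos_correction && length(va_idx) >= 10) {
      fwv <- lstm_forward(params, wd$inputs[va_idx, , , drop = FALSE], units)
      for (j in 1:4) {
        if (stats::var(fwv$y[, j]) > 1e-8) {
          fit <- stats::lm.fit(cbind(1, fwv$y[, j]), wd$targets[va_idx, j])
          mos[, j] <- fit$coefficients
        }
      }
    }

    structure(
      list(
        params = params,
        scaler = scaler,
        config = config,
        mos = mos,
        history = dplyr::bind_rows(history),
        train_tail = series[(n - L + 1):n, , drop = FALSE]
      ),
      class = "weather_forecaster"
    )
  })
}

#' @export
print.weather_forecaster <- function(x, ...) {
  cat(sprintf(
    "<weather_forecaster: %d-day window, %d LSTM units, %d epochs, best val loss %.3g>\n",
    x$config$window_length, x$config$lstm_units, nrow(x$history),
    min(x$history$val_loss, na.rm = TRUE)
  ))
  invisible(x)
}

#' Tidy the forecaster training history
#'
#' @param x A `weather_forecaster`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `val_loss`.
#' @method tidy weather_forecaster
#' @export
tidy.weather_forecaster <- function(x, ...) x$history

#' One-row forecaster summary
#'
#' @param x A `weather_forecaster`.
#' @param ... Unused.
#' @return Tibble with `epochs_run`, `final_loss`, `best_val_loss`.
#' @method glance weather_forecaster
#' @export
glance.weather_forecaster <- function(x, ...) {
  tibble(
    epochs_run = nrow(x$history),
    final_loss = x$history$loss[nrow(x$history)],
    best_val_loss = min(x$history$val_loss, na.rm = TRUE)
  )
}

#' Roll out a multi-day weather forecast
#'
#' Iterative multi-step forecasting: each predicted day is appended to the
#' window (and the oldest day dropped) to predict the following day. Output
#' is returned in physical units with humidity clipped to \[0, 100\] and
#' precipitation floored at 0.
#'
#' @param model A `weather_forecaster`.
#' @param history_window The last `window_length` observed days (weather
#'   series tibble); defaults to the tail of the training series.
#' @param horizon Days to forecast (>= 0).
#' @return A `forecast_series` tibble in the weather schema.
#' @export
forecast_weather <- function(model, history_window = NULL, horizon = NULL) {
  horizon <- if (is.null(horizon)) model$config$horizon else as.integer(horizon)
  if (horizon < 0) {
    abort("`horizon` must be >= 0.", class = "cropsense_validation_error")
  }
  if (is.null(history_window)) history_window <- model$train_tail
  history_window <- validate_weather_series(history_window)
  L <- model$config$window_length
  if (nrow(history_window) != L) {
    abort(
      sprintf("history_window must contain exactly %d days.", L),
      class = "cropsense_validation_error"
    )
  }
  dates <- as.Date(max(history_window$time)) + seq_len(horizon)
  out <- matrix(NA_real_, horizon, 4, dimnames = list(NULL, forecast_features()))
  if (horizon > 0) {
    W <- scale_features(as.matrix(history_window[forecast_features()]), model$scaler)
    units <- model$config$lstm_units
    mos <- model$mos %||% rbind(intercept = rep(0, 4), slope = rep(1, 4))
    for (d in seq_len(horizon)) {
      fw <- lstm_forward(model$params, array(W, c(1, L, 4)), units)
      y <- mos["intercept", ] + mos["slope", ] * fw$y[1, ]
      y <- pmin(pmax(y, -0.2), 1.2) # keep the fed-back state near the unit box
      out[d, ] <- y
      W <- rbind(W[-1, , drop = FALSE], matrix(y, 1))
    }
    out <- unscale_features(out, model$scaler)
    out[, "rel_humidity_2m"] <- pmin(pmax(out[, "rel_humidity_2m"], 0), 100)
    out[, "total_precip"] <- pmax(out[, "total_precip"], 0)
  }
  structure(
    tibble(
      time = dates,
      temperature_2m = out[, 1],
      rel_humidity_2m = out[, 2],
      total_precip = out[, 3],
      pressure = out[, 4]
    ),
    class = c("forecast_series", class(tibble()))
  )
}

#' Persistence baseline forecast
#'
#' Repeats the last observed day's values over the whole horizon — the naive
#' reference any skilful forecaster must beat.
#'
#' @param history_window Nonempty weather series tibble.
#' @param horizon Days to forecast (>= 0).
#' @return A `forecast_series` tibble.
#' @export
#' @examples
#' w <- generate_weather(weather_sim_params(n_days = 7))
#' persistence_baseline(w, 3)
persistence_baseline <- function(history_window, horizon) {
  if (is.null(history_window) || !nrow(history_window)) {
    abort("history_window must be nonempty.", class = "cropsense_validation_error")
  }
  history_window <- validate_weather_series(history_window)
  last <- history_window[nrow(history_window), ]
  dates <- as.Date(last$time) + seq_len(horizon)
  structure(
    tibble(
      time = dates,
      temperature_2m = rep(last$temperature_2m, horizon),
      rel_humidity_2m = rep(last$rel_humidity_2m, horizon),
      total_precip = rep(last$total_precip, horizon),
      pressure = rep(last$pressure, horizon)
    ),
    class = c("forecast_series", class(tibble()))
  )
}

#' Plot observed and forecast weather
#'
#' @param object A `forecast_series`.
#' @param observed Optional observed weather series to overlay.
#' @param ... Unused.
#' @return A ggplot object faceted by variable.
#' @method autoplot forecast_series
#' @export
autoplot.forecast_series <- function(object, observed = NULL, ...) {
  long <- function(df, kind) {
    tidyr::pivot_longer(
      dplyr::mutate(as_tibble(df), kind = kind),
      dplyr::all_of(forecast_features()),
      names_to = "variable", values_to = "value"
    )
  }
  df <- long(object, "forecast")
  if (!is.null(observed)) df <- dplyr::bind_rows(df, long(observed, "observed"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$value,
    colour = .data$kind
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
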