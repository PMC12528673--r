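#' Parameters for the daily weather simulator
#'
#' Defaults emulate the climate of an arid North-Egyptian agricultural
#' governorate: a sinusoidal annual temperature cycle with its minimum in
#' mid-January, relative humidity anticorrelated with temperature, sparse
#' light precipitation, and near-constant station-level pressure on the
#' ~100.8 scale of the station records the pipeline consumes (the pressure
#' unit is carried through unused by any rule).
#'
#' @param start_date First day of the series (`Date` or ISO string).
#' @param n_days Number of daily records (>= 1).
#' @param temp_mean Annual mean 2 m air temperature, degrees C.
#' @param temp_annual_amplitude Amplitude of the annual sinusoid, degrees C.
#' @param temp_noise_sd Daily temperature noise sd, degrees C.
#' @param humidity_base Mean relative humidity, percent.
#' @param humidity_temp_coupling Humidity drop per degree of temperature
#'   anomaly, percent per degree C (applied with a negative sign).
#' @param humidity_noise_sd Daily humidity noise sd, percent.
#' @param precip_wet_prob Probability that a day has any rain.
#' @param precip_scale Mean rainfall on wet days, mm/day.
#' @param pressure_mean Mean station pressure (unit-agnostic).
#' @param pressure_noise_sd Daily pressure noise sd (same unit).
#' @param seed Integer RNG seed.
#' @return A `weather_sim_params` object.
#' @export
weather_sim_params <- function(start_date = "2024-01-01",
                               n_days = 365,
                               temp_mean = 21,
                               temp_annual_amplitude = 8,
                               temp_noise_sd = 1,
                               humidity_base = 60,
                               humidity_temp_coupling = 1.5,
                               humidity_noise_sd = 8,
                               precip_wet_prob = 0.15,
                               precip_scale = 1,
                               pressure_mean = 100.8,
                               pressure_noise_sd = 0.3,
                               seed = 1) {
  n_days <- assert_count(n_days, "n_days")
  assert_scalar_number(temp_mean, "temp_mean")
  assert_scalar_number(temp_annual_amplitude, "temp_annual_amplitude", min = 0)
  assert_scalar_number(temp_noise_sd, "temp_noise_sd", min = 0)
  assert_scalar_number(humidity_base, "humidity_base", min = 0, max = 100)
  assert_scalar_number(humidity_noise_sd, "humidity_noise_sd", min = 0)
  assert_scalar_number(precip_wet_prob, "precip_wet_prob", min = 0, max = 1)
  assert_scalar_number(precip_scale, "precip_scale", min = 0)
  assert_scalar_number(pressure_noise_sd, "pressure_noise_sd", min = 0)
  structure(
    list(
      start_date = as.Date(start_date),
      n_days = n_days,
      temp_mean = temp_mean,
      temp_annual_amplitude = temp_annual_amplitude,
      temp_noise_sd = temp_noise_sd,
      humidity_base = humidity_base,
      humidity_temp_coupling = humidity_temp_coupling,
      humidity_noise_sd = humidity_noise_sd,
      precip_wet_prob = precip_wet_prob,
      precip_scale = precip_scale,
      pressure_mean = pressure_mean,
      pressure_noise_sd = pressure_noise_sd,
      seed = seed
    ),
    class = "weather_sim_params"
  )
}

# phase placing the annual temperature minimum around January 15
annual_phase <- function() -pi / 2 - 2 * pi * 15 / 365.25

#' Generate a synthetic daily weather series
#'
#' Daily temperature follows a seasonal sinusoid plus Gaussian noise;
#' relative humidity is the base level minus a linear coupling to the
#' temperature anomaly plus noise, clipped to \[0, 100\]; precipitation is a
#' Bernoulli-exponential mixture (dry with probability `1 - precip_wet_prob`,
#' otherwise exponential with mean `precip_scale`); pressure is Gaussian
#' around its mean. Timestamps are strictly increasing consecutive days, and
#' a fixed seed reproduces the series exactly.
#'
#' @param params A [weather_sim_params()].
#' @return A tibble (class `weather_series`) with columns `time`,
#'   `temperature_2m`, `rel_humidity_2m`, `total_precip`, `pressure`.
#' @export
#' @examples
#' w <- generate_weather(weather_sim_params(n_days = 30, seed = 7))
#' dplyr::summarise(w, mean_t = mean(temperature_2m))
generate_weather <- function(params) {
  if (!inherits(params, "weather_sim_params")) {
    abort("`params` must be weather_sim_params.", class = "cropsense_validation_error")
  }
  dates <- params$start_date + seq_len(params$n_days) - 1L
  doy <- as.numeric(format(dates, "%j"))
  with_seed(params$seed, {
    n <- params$n_days
    seasonal <- params$temp_annual_amplitude *
      sin(2 * pi * doy / 365.25 + annual_phase())
    temp <- params$temp_mean + seasonal + rnorm(n, 0, params$temp_noise_sd)
    hum <- params$humidity_base -
      params$humidity_temp_coupling * (temp - params$temp_mean) +
      rnorm(n, 0, params$humidity_noise_sd)
    hum <- pmin(pmax(hum, 0), 100)
    wet <- runif(n) < params$precip_wet_prob
    precip <- ifelse(wet & params$precip_scale > 0,
      rexp(n, rate = 1 / max(params$precip_scale, .Machine$double.eps)), 0
    )
    precip[!wet] <- 0
    pressure <- params$pressure_mean + rnorm(n, 0, params$pressure_noise_sd)
    new_weather_series(tibble(
      time = dates,
      temperature_2m = temp,
      rel_humidity_2m = hum,
      total_precip = precip,
      pressure = pressure
    ))
  })
}

weather_columns <- function() {
  c("time", "temperature_2m", "rel_humidity_2m", "total_precip", "pressure")
}

new_weather_series <- function(df) {
  structure(df, class = c("weather_series", class(tibble())))
}

#' Validate a daily weather series
#'
#' Checks the schema (time, temperature_2m, rel_humidity_2m, total_precip,
#' pressure), strictly increasing dates at daily spacing, humidity in
#' \[0, 100\] and nonnegative precipitation.
#'
#' @param series A data frame in the weather schema.
#' @return The series, invisibly, as a `weather_series` tibble.
#' @export
validate_weather_series <- function(series) {
  missing <- setdiff(weather_columns(), names(series))
  if (length(missing)) {
    abort(
      paste0("weather series missing columns: ", paste(missing, collapse = ", ")),
      class = "cropsense_validation_error"
    )
  }
  d <- as.Date(series$time)
  if (nrow(series) > 1) {
    gaps <- diff(as.integer(d))
    if (any(gaps != 1)) {
      first_gap <- which(gaps != 1)[1]
      abort(
        sprintf(
          "weather series must be consecutive daily records; first gap after %s.",
          format(d[first_gap])
        ),
        class = "cropsense_validation_error"
      )
    }
  }
  if (any(series$rel_humidity_2m < 0 | series$rel_humidity_2m > 100)) {
    abort("humidity must lie in [0, 100].", class = "cropsense_validation_error")
  }
  if (any(series$total_precip < 0)) {
    abort("precipitation must be nonnegative.", class = "cropsense_validation_error")
  }
  invisible(new_weather_series(as_tibble(series)))
}
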