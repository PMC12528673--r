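Package: cropsense
Title: Land-Suitability Classification, Weather Forecasting and Rule-Based Crop Recommendation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end crop-advisory pipeline for precision agriculture.
    Simulates Sentinel-2-like multispectral scenes and daily weather series,
    computes six spectral indices (NDVI, NDWI, Moisture, EVI, NDSI, GNDVI)
    and stacks them into a normalized multi-channel raster, classifies each
    pixel into high / low / not-suitable agricultural preference with a
    patch-based convolutional neural network, forecasts daily temperature,
    humidity, precipitation and pressure with a sliding-window LSTM, and
    combines the land class with the forecast through a deterministic
    IF-THEN crop-recommendation engine with agronomic thresholds.
    Includes classification and regression evaluation metrics, a persistence
    baseline for forecast skill, and a seeded, reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
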