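test_that("normalized difference obeys its closed form and symmetry", {
  m <- function(v) matrix(v, 2, 2)
  expect_true(all(normalized_difference(m(0.4), m(0.4))$values == 0))
  expect_true(all(normalized_difference(m(1), m(0))$values == 1))
  expect_true(all(normalized_difference(m(0), m(1))$values == -1))
  expect_equal(normalized_difference(m(0.8), m(0.2))$values, m(0.6))
  expect_error(
    normalized_difference(matrix(1, 2, 2), matrix(1, 3, 3)),
    class = "cropsense_validation_error"
  )
})

test_that("zero denominators are masked, not invented", {
  nd <- normalized_difference(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_true(all(nd$mask))
  expect_true(all(is.na(nd$values)))
})

test_that("antisymmetry and bounds hold on random reflectance grids", {
  set.seed(42)
  for (i in 1:20) {
    a <- matrix(runif(64), 8, 8)
    b <- matrix(runif(64), 8, 8)
    ab <- normalized_difference(a, b)
    ba <- normalized_difference(b, a)
    expect_equal(ab$values, -ba$values)
    expect_true(all(ab$values >= -1 & ab$values <= 1))
  }
})

test_that("each index follows its equation on a synthetic scene", {
  sc <- tiny_scene(8)
  g <- function(id) sc$bands[[id]]$values
  expect_equal(
    compute_index("NDVI", sc$bands)$values,
    (g("B08") - g("B04")) / (g("B08") + g("B04"))
  )
  expect_equal(
    compute_index("NDWI", sc$bands)$values,
    (g("B03") - g("B08")) / (g("B03") + g("B08"))
  )
  expect_equal(
    compute_index("MOISTURE", sc$bands)$values,
    (g("B8A") - g("B11")) / (g("B8A") + g("B11"))
  )
  expect_equal(
    compute_index("NDSI", sc$bands)$values,
    (g("B03") - g("B11")) / (g("B03") + g("B11"))
  )
  # GNDVI is the exact negation of NDWI
  expect_equal(
    compute_index("GNDVI", sc$bands)$values,
    -compute_index("NDWI", sc$bands)$values
  )
})

test_that("EVI reproduces the hand-computed example and honours constants", {
  bands <- list(
    B08 = band_raster("B08", matrix(0.5)),
    B04 = band_raster("B04", matrix(0.2)),
    B02 = band_raster("B02", matrix(0.1))
  )
  evi <- compute_index("EVI", bands)
  expect_equal(evi$values[1, 1], 2.5 * 0.3 / (0.5 + 6 * 0.2 - 7.5 * 0.1 + 1))
  expect_equal(round(evi$values[1, 1], 4), 0.3846)
  halved <- compute_index("EVI", bands, evi_constants(G = 1.25))
  expect_equal(halved$values[1, 1], evi$values[1, 1] / 2)
})

test_that("the literal reciprocal NDVI variant is available but not default", {
  bands <- list(
    B08 = band_raster("B08", matrix(0.5)),
    B04 = band_raster("B04", matrix(0.2))
  )
  std <- compute_index("NDVI", bands)
  lit <- compute_index("NDVI", bands, ndvi_as_printed = TRUE)
  expect_equal(std$values[1, 1], 0.3 / 0.7)
  expect_equal(lit$values[1, 1], 0.7 / 0.3)
})

test_that("missing bands produce a configuration error naming the band", {
  bands <- list(B08 = band_raster("B08", matrix(0.5)))
  expect_error(compute_index("NDVI", bands), "B04",
    class = "cropsense_config_error"
  )
})

test_that("min-max normalization covers identity, affine and degenerate cases", {
  id <- minmax_normalize(index_layer("NDVI", matrix(c(0, 0.25, 0.5, 1), 2)))
  expect_equal(id$layer$values, matrix(c(0, 0.25, 0.5, 1), 2))
  tri <- minmax_normalize(index_layer("NDVI", matrix(c(-1, 0, 1, 1), 2)))
  expect_equal(tri$layer$values, matrix(c(0, 0.5, 1, 1), 2))
  expect_warning(
    flat <- minmax_normalize(index_layer("EVI", matrix(0.7, 2, 2))),
    "constant"
  )
  expect_true(all(flat$layer$values == 0))
  expect_true(flat$params$degenerate)
  fully_masked <- index_layer("NDVI", matrix(1, 2, 2), matrix(TRUE, 2, 2))
  expect_error(minmax_normalize(fully_masked), class = "cropsense_validation_error")
})

test_that("denormalizing with the returned params recovers the input", {
  set.seed(1)
  vals <- matrix(rnorm(36, sd = 2), 6, 6)
  norm <- minmax_normalize(index_layer("EVI", vals))
  back <- minmax_denormalize(norm$layer$values, norm$params)
  expect_equal(back, vals, tolerance = 1e-12)
})

test_that("supplied scaler params are reused and clipped", {
  layer <- index_layer("NDVI", matrix(c(-0.5, 0, 0.5, 2), 2))
  norm <- minmax_normalize(layer, params = list(min = 0, max = 1))
  expect_equal(norm$layer$values, matrix(c(0, 0, 0.5, 1), 2))
  expect_equal(norm$params$min, 0)
  expect_equal(norm$params$max, 1)
})

test_that("stacking enforces order, grid and mask union", {
  stk <- tiny_stack()
  expect_identical(stk$channel_names, index_names())
  expect_true(all(stk$values >= 0 & stk$values <= 1, na.rm = TRUE))
  # wrong order rejected
  layers <- lapply(index_names(), function(nm) index_layer(nm, matrix(0.5, 2, 2)))
  expect_error(stack_layers(rev(layers)), class = "cropsense_validation_error")
  expect_error(stack_layers(layers[1:5]), class = "cropsense_validation_error")
  # mask union: a pixel masked in one layer is masked in the stack
  layers[[3]] <- index_layer("MOISTURE", matrix(0.5, 2, 2),
    nodata_mask = matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  )
  masked_stack <- stack_layers(layers)
  expect_true(masked_stack$nodata_mask[1, 1])
  expect_identical(sum(masked_stack$nodata_mask), 1L)
})

test_that("stack then channel-extract round-trips the layers", {
  stk <- tiny_stack()
  for (nm in index_names()) {
    layer <- stack_channel(stk, nm)
    i <- match(nm, index_names())
    expect_equal(layer$values, stk$values[, , i])
  }
  expect_error(stack_channel(stk, "SI"), class = "cropsense_validation_error")
})

test_that("single-pixel stacking keeps the value vector", {
  layers <- lapply(index_names(), function(nm) index_layer(nm, matrix(0.5)))
  stk <- stack_layers(layers)
  expect_equal(as.vector(stk$values[1, 1, ]), rep(0.5, 6))
})

test_that("composite pixel band sums match the worked examples", {
  expect_identical(class_pixel_band_sum(c(19, 237, 66)), 322L)
  expect_identical(class_pixel_band_sum(c(63, 54, 66)), 183L)
  expect_identical(class_pixel_band_sum(c(237, 57, 2)), 296L)
  expect_identical(class_pixel_band_sum(c(0, 0, 0)), 0L)
  expect_error(class_pixel_band_sum(c(1, 2)), class = "cropsense_validation_error")
  expect_error(class_pixel_band_sum(c(1, 2, 300)), class = "cropsense_validation_error")
})
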