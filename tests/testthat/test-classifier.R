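test_that("patch extraction honours the one-sample-per-pixel contract", {
  sc <- tiny_scene(10)
  stk <- tiny_stack(sc)
  for (p in c(1L, 3L, 5L)) {
    ds <- extract_patches(stk, sc$truth, p)
    expect_identical(length(ds$y), 100L)
    expect_identical(dim(ds$x), c(p, p, 6L, 100L))
  }
  # centre value of each patch equals the pixel's own stack value
  ds <- extract_patches(stk, sc$truth, 3)
  centre <- ds$x[2, 2, , 1]
  expect_equal(centre, as.vector(stk$values[ds$pixels$row[1], ds$pixels$col[1], ]))
  expect_error(extract_patches(stk, sc$truth, 4), class = "cropsense_validation_error")
  expect_error(extract_patches(stk, sc$truth, 21), class = "cropsense_validation_error")
})

test_that("corner patches mirror their neighbours by reflection", {
  vals <- matrix(as.numeric(1:16), 4, 4) # column-major 4x4
  layers <- lapply(index_names(), function(nm) {
    index_layer(nm, vals / 16)
  })
  stk <- stack_layers(layers)
  truth <- suitability_map(matrix("HIGH", 4, 4))
  ds <- extract_patches(stk, truth, 3)
  # sample 1 is pixel (1,1); its 3x3 patch rows/cols reflect index 2
  patch <- ds$x[, , 1, 1] * 16
  expect_equal(patch, rbind(
    c(6, 2, 6),
    c(5, 1, 5),
    c(6, 2, 6)
  ))
})

test_that("training requires every class and a matching patch size", {
  sc <- tiny_scene(12)
  stk <- tiny_stack(sc)
  ds <- extract_patches(stk, sc$truth, 5)
  only_high <- ds
  only_high$y <- rep(3L, length(ds$y))
  expect_error(
    train_classifier(only_high, fast_classifier_config(patch_size = 5)),
    "NOT_SUITABLE",
    class = "cropsense_validation_error"
  )
  expect_error(
    train_classifier(ds, fast_classifier_config(patch_size = 3)),
    class = "cropsense_config_error"
  )
})

test_that("config invariants are enforced", {
  expect_error(classifier_config(patch_size = 8), class = "cropsense_validation_error")
  expect_error(classifier_config(dropout_rate = 1), class = "cropsense_validation_error")
  expect_error(classifier_config(conv_filters = c(32, 64)), class = "cropsense_validation_error")
})

test_that("a single epoch yields a single history row", {
  sc <- tiny_scene(12)
  stk <- tiny_stack(sc)
  ds <- extract_patches(stk, sc$truth, 3)
  m <- train_classifier(ds, fast_classifier_config(patch_size = 3, max_epochs = 1))
  expect_identical(nrow(m$history), 1L)
  expect_true(all(m$history$loss >= 0))
})

test_that("training and prediction are deterministic under a fixed seed", {
  sc <- tiny_scene(12)
  stk <- tiny_stack(sc)
  ds <- extract_patches(stk, sc$truth, 3)
  cfg <- fast_classifier_config(patch_size = 3, seed = 5)
  m1 <- train_classifier(ds, cfg)
  m2 <- train_classifier(ds, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(predict_map(m1, stk)$labels, predict_map(m2, stk)$labels)
})

test_that("predicted maps satisfy the probability simplex and argmax contract", {
  sc <- tiny_scene(12)
  stk <- tiny_stack(sc)
  ds <- extract_patches(stk, sc$truth, 3)
  m <- train_classifier(ds, fast_classifier_config(patch_size = 3))
  map <- predict_map(m, stk)
  sums <- apply(map$probabilities, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(map$probabilities >= 0))
  argmax <- land_classes()[apply(map$probabilities, c(1, 2), which.max)]
  expect_identical(as.vector(map$labels), argmax)
  expect_true(all(map$labels %in% land_classes()))
})

test_that("channel or scaler mismatch at prediction is refused", {
  sc <- tiny_scene(12)
  stk <- tiny_stack(sc)
  ds <- extract_patches(stk, sc$truth, 3)
  m <- train_classifier(ds, fast_classifier_config(patch_size = 3), scaler = stk$scaler)
  other <- stk
  other$channel_names <- rev(stk$channel_names)
  expect_error(predict_map(m, other), class = "cropsense_config_error")
  shifted <- stk
  shifted$scaler$NDVI$max <- shifted$scaler$NDVI$max + 1
  expect_error(predict_map(m, shifted), "NDVI", class = "cropsense_config_error")
})

test_that("convolution, pooling and batch-norm gradients match finite differences", {
  set.seed(7)
  A <- array(rnorm(5 * 5 * 2 * 3), c(5, 5, 2, 3))
  Wf <- array(rnorm(18 * 4, sd = 0.2), c(3, 3, 2, 4))
  bf <- rnorm(4, sd = 0.1)
  idx <- cropsense:::conv_gather_index(5, 5, 2, 3, 1)
  loss <- function(a, w, b) sum(cropsense:::conv_forward(a, w, b, idx)$out^2) / 2
  fw <- cropsense:::conv_forward(A, Wf, bf, idx)
  bk <- cropsense:::conv_backward(fw$out, fw, Wf, idx)
  expect_lt(max(abs(numerical_gradient(function(w) loss(A, w, bf), Wf) - bk$dW)), 1e-6)
  expect_lt(max(abs(numerical_gradient(function(a) loss(a, Wf, bf), A) - bk$dA)), 1e-6)

  pf <- cropsense:::pool_forward(A)
  pb <- cropsense:::pool_backward(pf$out, pf)
  ploss <- function(a) sum(cropsense:::pool_forward(a)$out^2) / 2
  expect_lt(max(abs(numerical_gradient(ploss, A) - pb)), 1e-6)

  gamma <- runif(2, 0.5, 1.5)
  beta <- rnorm(2, sd = 0.1)
  run <- list(mean = rep(0, 2), var = rep(1, 2))
  bf2 <- cropsense:::bn_forward(A, gamma, beta, run, train = TRUE)
  bb <- cropsense:::bn_backward(bf2$out, bf2, gamma)
  bloss <- function(a) sum(cropsense:::bn_forward(a, gamma, beta, run, TRUE)$out^2) / 2
  expect_lt(max(abs(numerical_gradient(bloss, A, eps = 1e-5) - bb$dA)), 1e-5)

  X <- matrix(rnorm(12), 4, 3)
  y <- c(1L, 2L, 3L, 1L)
  sx <- cropsense:::softmax_xent(X, y)
  sloss <- function(x) cropsense:::softmax_xent(x, y)$loss
  expect_lt(max(abs(numerical_gradient(sloss, X) - sx$dlogits)), 1e-7)
})
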