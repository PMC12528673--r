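#' Configuration for the patch-based suitability classifier
#'
#' A compact convolutional network classifying the centre pixel of a
#' `patch_size x patch_size x 6` index-stack neighborhood into the three
#' land-suitability classes. The architecture is three convolutional layers
#' (default 32, 64, 128 filters), each followed by ReLU, 2x2 max pooling
#' (skipped automatically once the spatial extent is below 2) and batch
#' normalization, then two dense layers and a softmax head. Training uses
#' Adam, categorical cross-entropy, dropout after the first dense layer and
#' early stopping on validation loss.
#'
#' @param patch_size Odd patch edge length in pixels (default 9).
#' @param conv_filters Integer vector of three filter counts.
#' @param kernel_size Convolution kernel edge (odd, default 3).
#' @param dense_units Widths of the two dense layers.
#' @param learning_rate Adam step size (default 0.001).
#' @param dropout_rate Dropout probability in \[0, 1) (default 0.3).
#' @param batch_size Samples per optimizer step (default 32).
#' @param max_epochs Upper bound on training epochs.
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping (default 5).
#' @param validation_split Fraction of samples held out, stratified by class.
#' @param max_train_samples Cap on training samples after the split,
#'   stratified (default 1152, i.e. 36 steps per epoch at batch 32); `NULL`
#'   disables the cap.
#' @param seed Integer RNG seed governing initialization, shuffling, dropout.
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(patch_size = 9,
                              conv_filters = c(32, 64, 128),
                              kernel_size = 3,
                              dense_units = c(64, 32),
                              learning_rate = 0.001,
                              dropout_rate = 0.3,
                              batch_size = 32,
                              max_epochs = 30,
                              early_stopping_patience = 5,
                              validation_split = 0.2,
                              max_train_samples = 1152,
                              seed = 1) {
  patch_size <- assert_count(patch_size, "patch_size")
  if (patch_size %% 2 == 0) {
    abort("`patch_size` must be odd so a centre pixel exists.",
      class = "cropsense_validation_error"
    )
  }
  kernel_size <- assert_count(kernel_size, "kernel_size")
  if (kernel_size %% 2 == 0) {
    abort("`kernel_size` must be odd.", class = "cropsense_validation_error")
  }
  if (length(conv_filters) != 3) {
    abort("`conv_filters` must give three filter counts.",
      class = "cropsense_validation_error"
    )
  }
  if (length(dense_units) != 2) {
    abort("`dense_units` must give two layer widths.",
      class = "cropsense_validation_error"
    )
  }
  assert_scalar_number(dropout_rate, "dropout_rate", 0, 1 - 1e-9)
  assert_scalar_number(validation_split, "validation_split", 0.05, 0.5)
  structure(
    list(
      patch_size = patch_size,
      conv_filters = as.integer(conv_filters),
      kernel_size = kernel_size,
      dense_units = as.integer(dense_units),
      n_classes = 3L,
      learning_rate = learning_rate,
      dropout_rate = dropout_rate,
      batch_size = assert_count(batch_size, "batch_size"),
      max_epochs = assert_count(max_epochs, "max_epochs"),
      early_stopping_patience = assert_count(early_stopping_patience,
        "early_stopping_patience",
        min = 1L
      ),
      validation_split = validation_split,
      max_train_samples = if (is.null(max_train_samples)) {
        NULL
      } else {
        assert_count(max_train_samples, "max_train_samples", min = 30L)
      },
      seed = seed
    ),
    class = "classifier_config"
  )
}

# reflection-padded index sequence of length n + 2r (mirror, edge not
# repeated): e.g. n = 4, r = 2 gives 3 2 | 1 2 3 4 | 3 2. Requires r <= n - 1,
# guaranteed because patch_size <= scene extent.
reflect_index <- function(n, r) {
  if (r == 0) {
    return(seq_len(n))
  }
  if (n == 1) {
    return(rep(1L, 1 + 2 * r))
  }
  c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
}

#' Extract labelled training patches from an index stack
#'
#' One sample per unmasked pixel: the `patch_size` square neighborhood of
#' the six-channel stack (input) and the centre pixel's ground-truth class
#' (target). Edges are handled by reflection padding so coverage is
#' complete.
#'
#' @param stack An `index_stack`.
#' @param truth A [suitability_map()] aligned with the stack.
#' @param patch_size Odd patch edge length.
#' @return A `patch_dataset`: list with `x` (patch, patch, 6, n array),
#'   `y` (integer class index 1..3 in [land_classes()] order), `pixels`
#'   (tibble of row/col), `channel_names`, `patch_size`.
#' @export
extract_patches <- function(stack, truth, patch_size = 9) {
  patch_size <- assert_count(patch_size, "patch_size")
  if (patch_size %% 2 == 0) {
    abort("`patch_size` must be odd.", class = "cropsense_validation_error")
  }
  d <- dim(stack$values)
  assert_same_dim(stack$nodata_mask, truth$labels, "stack and truth")
  if (patch_size > min(d[1:2])) {
    abort("patch larger than the scene.", class = "cropsense_validation_error")
  }
  r <- (patch_size - 1L) %/% 2L
  ri <- reflect_index(d[1], r)
  ci <- reflect_index(d[2], r)
  P <- stack$values[ri, ci, , drop = FALSE]
  P[is.na(P)] <- 0 # masked pixels contribute nothing; centres are unmasked
  idx <- conv_gather_index(d[1], d[2], d[3], patch_size, r)
  dim(P) <- c(prod(dim(P)[1:3]), 1L)
  X <- matrix(P[as.vector(idx), 1], nrow(idx), ncol(idx)) # (p*p*6, H*W)
  keep <- which(!(stack$nodata_mask | truth$nodata_mask))
  X <- X[, keep, drop = FALSE]
  x <- array(X, c(patch_size, patch_size, d[3], length(keep)))
  rows <- ((keep - 1L) %% d[1]) + 1L
  cols <- ((keep - 1L) %/% d[1]) + 1L
  y <- match(truth$labels[keep], land_classes())
  structure(
    list(
      x = x, y = y,
      pixels = tibble(row = rows, col = cols),
      channel_names = stack$channel_names,
      patch_size = patch_size
    ),
    class = "patch_dataset"
  )
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf(
    "<patch_dataset: %d samples of %d x %d x %d>\n",
    length(x$y), x$patch_size, x$patch_size, dim(x$x)[3]
  ))
  invisible(x)
}

# ---- architecture ---------------------------------------------------------

build_cnn_arch <- function(patch_size, n_channels, config) {
  spatial <- patch_size
  c_in <- n_channels
  conv <- list()
  for (l in 1:3) {
    f <- config$conv_filters[l]
    pool <- spatial >= 2
    conv[[l]] <- list(
      k = config$kernel_size, c_in = c_in, f = f, spatial = spatial, pool = pool,
      idx = conv_gather_index(spatial, spatial, c_in, config$kernel_size,
        p = (config$kernel_size - 1) %/% 2
      )
    )
    if (pool) spatial <- spatial %/% 2
    c_in <- f
  }
  list(
    conv = conv,
    flat_dim = spatial * spatial * c_in,
    final_spatial = spatial,
    dense_units = config$dense_units,
    n_classes = config$n_classes
  )
}

init_cnn_params <- function(arch) {
  params <- list()
  for (l in 1:3) {
    cv <- arch$conv[[l]]
    fan_in <- cv$k^2 * cv$c_in
    params[[paste0("W", l)]] <- glorot_uniform(fan_in, cv$f, c(cv$k, cv$k, cv$c_in, cv$f))
    params[[paste0("b", l)]] <- rep(0, cv$f)
    params[[paste0("g", l)]] <- rep(1, cv$f)
    params[[paste0("be", l)]] <- rep(0, cv$f)
  }
  dims <- c(arch$flat_dim, arch$dense_units, arch$n_classes)
  for (l in 1:3) {
    params[[paste0("DW", l)]] <- glorot_uniform(
      dims[l], dims[l + 1], c(dims[l], dims[l + 1])
    )
    params[[paste0("Db", l)]] <- rep(0, dims[l + 1])
  }
  params
}

init_bn_running <- function(arch) {
  lapply(1:3, function(l) {
    list(mean = rep(0, arch$conv[[l]]$f), var = rep(1, arch$conv[[l]]$f))
  })
}

cnn_forward <- function(params, arch, running, X, config, train) {
  caches <- list()
  A <- X
  for (l in 1:3) {
    cv <- arch$conv[[l]]
    cf <- conv_forward(A, params[[paste0("W", l)]], params[[paste0("b", l)]], cv$idx)
    rl <- relu_forward(cf$out)
    A <- rl$out
    pl <- NULL
    if (cv$pool) {
      pl <- pool_forward(A)
      A <- pl$out
    }
    bn <- bn_forward(
      A, params[[paste0("g", l)]], params[[paste0("be", l)]],
      running[[l]], train
    )
    if (train) running[[l]] <- bn$running
    A <- bn$out
    caches[[l]] <- list(conv = cf, relu = rl, pool = pl, bn = bn)
  }
  B <- dim(A)[4]
  flat_dim <- prod(dim(A)[1:3])
  Xf <- t(matrix(A, flat_dim, B))
  d1 <- dense_forward(Xf, params$DW1, params$Db1)
  r1 <- relu_forward(d1$out)
  dr <- dropout_forward(r1$out, config$dropout_rate, train)
  d2 <- dense_forward(dr$out, params$DW2, params$Db2)
  r2 <- relu_forward(d2$out)
  d3 <- dense_forward(r2$out, params$DW3, params$Db3)
  list(
    logits = d3$out,
    running = running,
    caches = list(
      conv = caches, flat_dim = flat_dim, conv_out_dim = dim(A),
      d1 = d1, r1 = r1, dr = dr, d2 = d2, r2 = r2, d3 = d3
    )
  )
}

cnn_backward <- function(dlogits, params, arch, caches) {
  grads <- list()
  b3 <- dense_backward(dlogits, caches$d3, params$DW3)
  grads$DW3 <- b3$dW
  grads$Db3 <- b3$db
  dx <- relu_backward(b3$dX, caches$r2)
  b2 <- dense_backward(dx, caches$d2, params$DW2)
  grads$DW2 <- b2$dW
  grads$Db2 <- b2$db
  dx <- dropout_backward(b2$dX, caches$dr)
  dx <- relu_backward(dx, caches$r1)
  b1 <- dense_backward(dx, caches$d1, params$DW1)
  grads$DW1 <- b1$dW
  grads$Db1 <- b1$db
  dA <- array(t(b1$dX), caches$conv_out_dim)
  for (l in 3:1) {
    cc <- caches$conv[[l]]
    bnb <- bn_backward(dA, cc$bn, params[[paste0("g", l)]])
    grads[[paste0("g", l)]] <- bnb$dgamma
    grads[[paste0("be", l)]] <- bnb$dbeta
    dA <- bnb$dA
    if (!is.null(cc$pool)) dA <- pool_backward(dA, cc$pool)
    dA <- relu_backward(dA, cc$relu)
    cvb <- conv_backward(dA, cc$conv, params[[paste0("W", l)]], arch$conv[[l]]$idx)
    grads[[paste0("W", l)]] <- cvb$dW
    grads[[paste0("b", l)]] <- cvb$db
    dA <- cvb$dA
  }
  grads
}

stratified_indices <- function(y, frac) {
  unlist(lapply(unique(y), function(cls) {
    i <- which(y == cls)
    sample(i, max(1L, round(length(i) * frac)))
  }), use.names = FALSE)
}

#' Train the suitability classifier
#'
#' Stratified 80/20 train/validation split by pixel, Adam on categorical
#' cross-entropy, dropout regularization, early stopping on validation loss
#' with best-weight restore. Reproducible under the config seed.
#'
#' @param dataset A `patch_dataset` from [extract_patches()].
#' @param config A [classifier_config()].
#' @param scaler Optional per-channel scaler params (recorded on the model so
#'   inference can verify the stack statistics).
#' @return A `suitability_model` with elements `params`, `running` (batch-norm
#'   statistics), `arch`, `config`, `history` (tibble of per-epoch losses),
#'   `channel_names`, `scaler`, `val_accuracy`, `val_indices`.
#' @export
train_classifier <- function(dataset, config = classifier_config(), scaler = NULL) {
  if (!inherits(dataset, "patch_dataset")) {
    abort("`dataset` must come from extract_patches().",
      class = "cropsense_validation_error"
    )
  }
  present <- sort(unique(dataset$y))
  absent <- setdiff(1:3, present)
  if (length(absent)) {
    abort(
      paste0(
        "class(es) absent from training data: ",
        paste(land_classes()[absent], collapse = ", ")
      ),
      class = "cropsense_validation_error"
    )
  }
  if (dim(dataset$x)[1] != config$patch_size) {
    abort("dataset patch size does not match the config.",
      class = "cropsense_config_error"
    )
  }
  arch <- build_cnn_arch(config$patch_size, dim(dataset$x)[3], config)

  with_seed(config$seed, {
    n <- length(dataset$y)
    val_idx <- sort(stratified_indices(dataset$y, config$validation_split))
    train_idx <- setdiff(seq_len(n), val_idx)
    if (!is.null(config$max_train_samples) &&
      length(train_idx) > config$max_train_samples) {
      keep_frac <- config$max_train_samples / length(train_idx)
      y_tr <- dataset$y[train_idx]
      train_idx <- sort(train_idx[stratified_indices(y_tr, keep_frac)])
    }
    params <- init_cnn_params(arch)
    running <- init_bn_running(arch)
    opt <- adam_init(params)
    best <- list(loss = Inf, params = params, running = running, epoch = 0L)
    history <- list()
    wait <- 0L

    eval_set <- function(idx) {
      # forward in inference mode, batched
      total_loss <- 0
      correct <- 0
      for (chunk in split(idx, ceiling(seq_along(idx) / 256))) {
        Xb <- dataset$x[, , , chunk, drop = FALSE]
        fw <- cnn_forward(params, arch, running, Xb, config, train = FALSE)
        sx <- softmax_xent(fw$logits, dataset$y[chunk])
        total_loss <- total_loss + sx$loss * length(chunk)
        correct <- correct + sum(max.col(sx$probs) == dataset$y[chunk])
      }
      c(loss = total_loss / length(idx), acc = correct / length(idx))
    }

    for (epoch in seq_len(config$max_epochs)) {
      order <- sample(train_idx)
      batches <- split(order, ceiling(seq_along(order) / config$batch_size))
      epoch_loss <- 0
      for (b in batches) {
        Xb <- dataset$x[, , , b, drop = FALSE]
        fw <- cnn_forward(params, arch, running, Xb, config, train = TRUE)
        running <- fw$running
        sx <- softmax_xent(fw$logits, dataset$y[b])
        epoch_loss <- epoch_loss + sx$loss * length(b)
        grads <- cnn_backward(sx$dlogits, params, arch, fw$caches)
        step <- adam_step(params, grads, opt, lr = config$learning_rate)
        params <- step$params
        opt <- step$state
      }
      epoch_loss <- epoch_loss / length(order)
      val <- eval_set(val_idx)
      history[[epoch]] <- tibble(
        epoch = epoch, loss = epoch_loss,
        val_loss = val[["loss"]], val_accuracy = val[["acc"]]
      )
      if (val[["loss"]] < best$loss - 1e-6) {
        best <- list(
          loss = val[["loss"]], params = params,
          running = running, epoch = epoch
        )
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stopping_patience) break
      }
    }
    params <- best$params
    running <- best$running
    final_val <- eval_set(val_idx)

    structure(
      list(
        params = params,
        running = running,
        arch = arch,
        config = config,
        history = dplyr::bind_rows(history),
        channel_names = dataset$channel_names,
        scaler = scaler,
        val_accuracy = final_val[["acc"]],
        val_indices = val_idx
      ),
      class = "suitability_model"
    )
  })
}

#' @export
print.suitability_model <- function(x, ...) {
  cat(sprintf(
    "<suitability_model: %d-patch CNN (%s filters), %d epochs, val accuracy %.3f>\n",
    x$config$patch_size, paste(x$config$conv_filters, collapse = "/"),
    nrow(x$history), x$val_accuracy
  ))
  invisible(x)
}

#' Tidy the training history of a suitability model
#'
#' @param x A `suitability_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`, `val_loss`, `val_accuracy`.
#' @method tidy suitability_model
#' @export
tidy.suitability_model <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x A `suitability_model`.
#' @param ... Unused.
#' @return Tibble with `epochs_run`, `final_loss`, `final_val_loss`,
#'   `val_accuracy`.
#' @method glance suitability_model
#' @export
glance.suitability_model <- function(x, ...) {
  tibble(
    epochs_run = nrow(x$history),
    final_loss = x$history$loss[nrow(x$history)],
    final_val_loss = x$history$val_loss[nrow(x$history)],
    val_accuracy = x$val_accuracy
  )
}

# forward a plain patch array through a trained model (inference mode)
predict_patches <- function(model, x) {
  n <- dim(x)[4]
  probs <- matrix(NA_real_, n, 3)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / 512))) {
    Xb <- x[, , , chunk, drop = FALSE]
    fw <- cnn_forward(model$params, model$arch, model$running, Xb,
      model$config,
      train = FALSE
    )
    probs[chunk, ] <- softmax_probs(fw$logits)
  }
  probs
}

#' Predict a full suitability map
#'
#' Classifies every unmasked pixel of an index stack with a trained model,
#' returning the label raster plus per-class probability channels. Masked
#' pixels stay masked.
#'
#' @param model A `suitability_model`.
#' @param stack An `index_stack` whose channels (and, when recorded, scaler
#'   statistics) match the training stack.
#' @return A [suitability_map()] with probabilities.
#' @export
predict_map <- function(model, stack) {
  if (!identical(stack$channel_names, model$channel_names)) {
    abort("stack channels do not match the channels the model was trained on.",
      class = "cropsense_config_error"
    )
  }
  if (!is.null(model$scaler) && !is.null(stack$scaler)) {
    for (nm in names(model$scaler)) {
      ms <- model$scaler[[nm]]
      ss <- stack$scaler[[nm]]
      if (!is.null(ss) &&
        (abs(ms$min - ss$min) > 1e-9 || abs(ms$max - ss$max) > 1e-9)) {
        abort(
          sprintf("channel %s was normalized with different scaler params.", nm),
          class = "cropsense_config_error"
        )
      }
    }
  }
  d <- dim(stack$values)
  truth_dummy <- suitability_map(
    matrix("NOT_SUITABLE", d[1], d[2]),
    nodata_mask = stack$nodata_mask, georef = stack$georef
  )
  ds <- extract_patches(stack, truth_dummy, model$config$patch_size)
  probs <- predict_patches(model, ds$x)
  labels <- matrix(NA_character_, d[1], d[2])
  parr <- array(NA_real_, c(d[1], d[2], 3))
  lin <- (ds$pixels$col - 1L) * d[1] + ds$pixels$row
  labels[lin] <- land_classes()[max.col(probs, ties.method = "first")]
  for (k in 1:3) {
    pk <- parr[, , k]
    pk[lin] <- probs[, k]
    parr[, , k] <- pk
  }
  labels[stack$nodata_mask] <- "NOT_SUITABLE" # placeholder under the mask
  suitability_map(labels,
    probabilities = parr,
    nodata_mask = stack$nodata_mask, georef = stack$georef
  )
}
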