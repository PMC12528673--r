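# Internal neural-network engine: minimal, vectorized implementations of the
# layers the suitability classifier and weather forecaster need (2-D
# convolution via im2col, 2x2 max pooling, batch normalization, dense layers,
# dropout, softmax cross-entropy) plus the Adam optimizer. Batches are 4-D
# arrays A[h, w, c, b]; dense activations are matrices (batch x features).
# Everything is plain double arithmetic so runs are reproducible under a
# fixed RNG seed.

glorot_uniform <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -limit, limit), dims)
}

# ---- im2col gather indices -------------------------------------------------

# Flat indices (within one sample's padded H x W x C volume) of the k x k x C
# neighborhood of every output position, for 'same' convolution with pad p.
# idx[r, pos]: r runs over (di, dj, c) with di fastest — matching the filter
# array layout (k, k, C, F) flattened column-major.
conv_gather_index <- function(H, W, C, k, p) {
  Hp <- H + 2 * p
  pos_i <- rep(seq_len(H), times = W)
  pos_j <- rep(seq_len(W), each = H)
  off_i <- rep(seq_len(k) - 1L, times = k * C)
  off_j <- rep(rep(seq_len(k) - 1L, each = k), times = C)
  off_c <- rep(seq_len(C) - 1L, each = k * k)
  ii <- outer(off_i, pos_i - 1L, `+`) + 1L # (k*k*C, H*W), padded row index
  jj <- outer(off_j, pos_j - 1L, `+`) + 1L
  cc <- matrix(off_c + 1L, k * k * C, H * W)
  ii + (jj - 1L) * Hp + (cc - 1L) * Hp * (W + 2 * p)
}

pad_batch <- function(A, p) {
  if (p == 0) {
    return(A)
  }
  d <- dim(A)
  P <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  P[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- A
  P
}

# ---- convolution -----------------------------------------------------------

conv_forward <- function(A, Wf, bf, idx) {
  d <- dim(A) # H, W, C, B
  k <- dim(Wf)[1]
  Fo <- dim(Wf)[4]
  p <- (k - 1) %/% 2
  P <- pad_batch(A, p)
  dim(P) <- c(prod(dim(P)[1:3]), d[4])
  cols <- P[as.vector(idx), , drop = FALSE] # (kkC*HW, B)
  kkC <- nrow(idx)
  HW <- ncol(idx)
  dim(cols) <- c(kkC, HW * d[4])
  Wm <- matrix(Wf, kkC, Fo)
  Y <- crossprod(cols, Wm) # (HW*B, F)
  Y <- sweep(Y, 2, bf, `+`)
  dim(Y) <- c(HW, d[4], Fo)
  Y <- aperm(Y, c(1, 3, 2)) # (HW, F, B)
  dim(Y) <- c(d[1], d[2], Fo, d[4])
  list(out = Y, cols = cols, in_dim = d)
}

conv_backward <- function(dY, cache, Wf, idx) {
  d <- cache$in_dim
  k <- dim(Wf)[1]
  Fo <- dim(Wf)[4]
  p <- (k - 1) %/% 2
  kkC <- nrow(idx)
  HW <- ncol(idx)
  dim(dY) <- c(HW, Fo, d[4])
  dY <- aperm(dY, c(1, 3, 2)) # (HW, B, F)
  dim(dY) <- c(HW * d[4], Fo)
  Wm <- matrix(Wf, kkC, Fo)
  dW <- cache$cols %*% dY # (kkC, F)
  db <- colSums(dY)
  dcols <- Wm %*% t(dY) # (kkC, HW*B)
  dim(dcols) <- c(kkC * HW, d[4])
  gi <- as.vector(idx)
  rs <- rowsum(dcols, gi) # rows sorted by unique gi
  Hp <- d[1] + 2 * p
  Wp <- d[2] + 2 * p
  dP <- matrix(0, Hp * Wp * d[3], d[4])
  dP[as.integer(rownames(rs)), ] <- rs
  dim(dP) <- c(Hp, Wp, d[3], d[4])
  dA <- dP[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  list(dA = dA, dW = array(dW, dim(Wf)), db = db)
}

# ---- 2x2 max pooling (stride 2, trailing odd row/col dropped) -------------

pool_forward <- function(A) {
  d <- dim(A)
  Ho <- d[1] %/% 2
  Wo <- d[2] %/% 2
  r1 <- seq_len(Ho) * 2 - 1
  c1 <- seq_len(Wo) * 2 - 1
  a11 <- A[r1, c1, , , drop = FALSE]
  a21 <- A[r1 + 1, c1, , , drop = FALSE]
  a12 <- A[r1, c1 + 1, , , drop = FALSE]
  a22 <- A[r1 + 1, c1 + 1, , , drop = FALSE]
  M <- pmax(a11, a21, a12, a22)
  m11 <- a11 == M
  m21 <- a21 == M & !m11
  m12 <- a12 == M & !m11 & !m21
  m22 <- a22 == M & !m11 & !m21 & !m12
  list(out = M, masks = list(m11, m21, m12, m22), in_dim = d)
}

pool_backward <- function(dM, cache) {
  d <- cache$in_dim
  Ho <- d[1] %/% 2
  Wo <- d[2] %/% 2
  r1 <- seq_len(Ho) * 2 - 1
  c1 <- seq_len(Wo) * 2 - 1
  dA <- array(0, d)
  z <- array(0, dim(dM))
  put <- function(mask) {
    g <- z
    g[mask] <- dM[mask]
    g
  }
  dA[r1, c1, , ] <- put(cache$masks[[1]])
  dA[r1 + 1, c1, , ] <- put(cache$masks[[2]])
  dA[r1, c1 + 1, , ] <- put(cache$masks[[3]])
  dA[r1 + 1, c1 + 1, , ] <- put(cache$masks[[4]])
  dA
}

# ---- batch normalization (per channel over H, W, B) ------------------------

bn_forward <- function(A, gamma, beta, running, train, momentum = 0.9, eps = 1e-5) {
  d <- dim(A)
  X <- aperm(A, c(1, 2, 4, 3))
  dim(X) <- c(d[1] * d[2] * d[4], d[3]) # (N, C)
  if (train) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2, mu)^2)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2, mu), 2, invstd, `*`)
  Y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(Y) <- c(d[1], d[2], d[4], d[3])
  list(
    out = aperm(Y, c(1, 2, 4, 3)), xhat = xhat, invstd = invstd,
    running = running, in_dim = d
  )
}

bn_backward <- function(dY, cache, gamma) {
  d <- cache$in_dim
  dYm <- aperm(dY, c(1, 2, 4, 3))
  dim(dYm) <- c(d[1] * d[2] * d[4], d[3])
  N <- nrow(dYm)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2, gamma, `*`)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dX <- sweep(t1 - t2, 2, cache$invstd, `*`)
  dim(dX) <- c(d[1], d[2], d[4], d[3])
  list(dA = aperm(dX, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

# ---- dense / activations / dropout ----------------------------------------

dense_forward <- function(X, W, b) {
  list(out = sweep(X %*% W, 2, b, `+`), X = X)
}

dense_backward <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = t(cache$X) %*% dY, db = colSums(dY))
}

relu_forward <- function(X) list(out = pmax(X, 0), mask = X > 0)

relu_backward <- function(dY, cache) dY * cache$mask

dropout_forward <- function(X, rate, train) {
  if (!train || rate <= 0) {
    return(list(out = X, mask = NULL))
  }
  mask <- (matrix(runif(length(X)), nrow(X)) >= rate) / (1 - rate)
  list(out = X * mask, mask = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy loss and logit gradient; y is an integer class index (1-based)
softmax_xent <- function(logits, y) {
  p <- softmax_probs(logits)
  n <- nrow(p)
  picked <- p[cbind(seq_len(n), y)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
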