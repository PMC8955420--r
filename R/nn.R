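# Native neural-network engine.
#
# No deep-learning framework ships with the target environment, so the
# small CNN and the dense softmax head are implemented directly on
# BLAS-backed matrix operations. A valid 3x3 convolution over a batch is
# one im2col GEMM. Internally the conv stack keeps batches in
# (H, W, N, C) layout — examples on the third axis, maps on the fourth —
# so that building the patch matrix and reshaping the GEMM output are
# plain `dim<-` reinterpretations with no array permutation; the only
# aperm left is one small transpose at the flatten stage. Gradients are
# checked against finite differences in the test suite.

# X: (H, W, N, C). Patch matrix: one row per (out_h, out_w, n), one column
# per kernel tap, channel-fastest within each (di, dj) offset block.
conv_im2col <- function(X, outh, outw) {
  d <- dim(X); N <- d[3]; C <- d[4]
  M <- matrix(0, outh * outw * N, 9L * C)
  b <- 0L
  for (dj in 1:3) for (di in 1:3) {
    Xs <- X[di:(di + outh - 1L), dj:(dj + outw - 1L), , , drop = FALSE]
    M[, (b * C + 1L):(b * C + C)] <- Xs
    b <- b + 1L
  }
  M
}

# kernel array (3,3,C,F) -> (9C x F) matrix matching conv_im2col columns
conv_wmat <- function(W) {
  d <- dim(W)
  matrix(aperm(W, c(3, 1, 2, 4)), nrow = 9L * d[3])
}

conv_wmat_inv <- function(Wmat, C, F) {
  aperm(array(Wmat, c(C, 3, 3, F)), c(2, 3, 1, 4))
}

# returns Y in (outh, outw, N, F) layout
conv2d_fwd <- function(X, W, b, keep_cols = FALSE) {
  d <- dim(X); N <- d[3]
  F <- dim(W)[4]
  outh <- d[1] - 2L; outw <- d[2] - 2L
  M <- conv_im2col(X, outh, outw)
  Y <- sweep(M %*% conv_wmat(W), 2, b, "+")
  dim(Y) <- c(outh, outw, N, F)
  list(Y = Y, M = if (keep_cols) M else NULL)
}

# M: cached im2col matrix of the layer input; in_dim: dim of that input.
# dOut: (outh, outw, N, F). need_dx = FALSE skips the input gradient
# (the first conv layer never needs one).
conv2d_bwd <- function(M, W, dOut, in_dim, need_dx = TRUE) {
  C <- in_dim[4]; N <- in_dim[3]
  F <- dim(W)[4]
  outh <- dim(dOut)[1]; outw <- dim(dOut)[2]
  Dm <- matrix(dOut, ncol = F)
  dW <- conv_wmat_inv(crossprod(M, Dm), C, F)
  db <- colSums(Dm)
  if (!need_dx) return(list(dX = NULL, dW = dW, db = db))
  dM <- tcrossprod(Dm, conv_wmat(W))
  dX <- array(0, in_dim)
  b <- 0L
  for (dj in 1:3) for (di in 1:3) {
    ri <- di:(di + outh - 1L); rj <- dj:(dj + outw - 1L)
    blk <- dM[, (b * C + 1L):(b * C + C)]
    dim(blk) <- c(outh, outw, N, C)
    dX[ri, rj, , ] <- dX[ri, rj, , , drop = FALSE] + blk
    b <- b + 1L
  }
  list(dX = dX, dW = dW, db = db)
}

# X: (H, W, N, C); 2x2 stride-2 max, floor division (odd trailing
# row/column dropped). Masks are only materialised when training.
maxpool_fwd <- function(X, need_masks = FALSE) {
  d <- dim(X); ph <- d[1] %/% 2L; pw <- d[2] %/% 2L
  i1 <- seq(1L, 2L * ph, 2L); j1 <- seq(1L, 2L * pw, 2L)
  A <- X[i1, j1, , , drop = FALSE]; B <- X[i1 + 1L, j1, , , drop = FALSE]
  Cs <- X[i1, j1 + 1L, , , drop = FALSE]; D <- X[i1 + 1L, j1 + 1L, , , drop = FALSE]
  Y <- pmax(A, B, Cs, D)
  masks <- NULL
  if (need_masks) {
    mA <- (A == Y); mB <- (B == Y) & !mA
    mC <- (Cs == Y) & !(mA | mB); mD <- !(mA | mB | mC)
    masks <- list(mA, mB, mC, mD)
  }
  list(Y = Y, masks = masks, in_dim = d)
}

maxpool_bwd <- function(pool, dY) {
  d <- pool$in_dim
  ph <- dim(dY)[1]; pw <- dim(dY)[2]
  i1 <- seq(1L, 2L * ph, 2L); j1 <- seq(1L, 2L * pw, 2L)
  dX <- array(0, d)
  dX[i1, j1, , ] <- dY * pool$masks[[1]]
  dX[i1 + 1L, j1, , ] <- dY * pool$masks[[2]]
  dX[i1, j1 + 1L, , ] <- dY * pool$masks[[3]]
  dX[i1 + 1L, j1 + 1L, , ] <- dY * pool$masks[[4]]
  dX
}

# (H, W, N, C) -> N x (H*W*C), feature order (h, w, c)
flatten_fwd <- function(X) {
  d <- dim(X)
  t(matrix(aperm(X, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3]))
}

flatten_bwd <- function(dFl, out_dim) {
  d <- out_dim
  aperm(array(t(dFl), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

he_init <- function(fan_in, dims) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

nn_init_params <- function(model) {
  p <- list()
  if (model$type == "cnn") {
    K <- model$input_shape[3]
    c1 <- model$cnn$conv1_maps; c2 <- model$cnn$conv2_maps
    p$W1 <- he_init(9 * K, c(3, 3, K, c1)); p$b1 <- numeric(c1)
    p$W2 <- he_init(9 * c1, c(3, 3, c1, c2)); p$b2 <- numeric(c2)
    d_in <- model$flatten_length
  } else {
    d_in <- model$input_shape
  }
  units <- model$head$hidden_units
  prev <- d_in
  for (i in seq_along(units)) {
    p[[paste0("Wh", i)]] <- he_init(prev, c(prev, units[i]))
    p[[paste0("bh", i)]] <- numeric(units[i])
    prev <- units[i]
  }
  p$Wout <- he_init(prev, c(prev, model$n_classes))
  p$bout <- numeric(model$n_classes)
  p
}

# Full forward pass. X arrives in user layout (H, W, K, N) for the CNN and
# is permuted once into the internal (H, W, N, K) layout. training=TRUE
# applies inverted dropout after each pooling stage and caches what the
# backward pass needs (im2col matrices, ReLU signs, pooling masks).
nn_forward <- function(model, X, params = model$params, training = FALSE) {
  cache <- list()
  if (model$type == "cnn") {
    stopifnot(length(dim(X)) == 4L)
    if (!all(dim(X)[1:3] == model$input_shape))
      stop("input shape ", paste(dim(X)[1:3], collapse = "x"),
           " does not match model input ",
           paste(model$input_shape, collapse = "x"))
    rate <- model$cnn$dropout_rate
    Xi <- aperm(X, c(1, 2, 4, 3))
    cache$in_dim1 <- dim(Xi)
    cv1 <- conv2d_fwd(Xi, params$W1, params$b1, keep_cols = training)
    cache$M1 <- cv1$M
    A1 <- pmax(cv1$Y, 0)
    if (training) cache$Z1pos <- (cv1$Y > 0)
    P1 <- maxpool_fwd(A1, need_masks = training); cache$P1 <- P1
    H1 <- P1$Y
    if (training && rate > 0) {
      cache$D1 <- array((runif(length(H1)) >= rate) / (1 - rate), dim(H1))
      H1 <- H1 * cache$D1
    }
    cache$in_dim2 <- dim(H1)
    cv2 <- conv2d_fwd(H1, params$W2, params$b2, keep_cols = training)
    cache$M2 <- cv2$M
    A2 <- pmax(cv2$Y, 0)
    if (training) cache$Z2pos <- (cv2$Y > 0)
    P2 <- maxpool_fwd(A2, need_masks = training); cache$P2 <- P2
    H2 <- P2$Y
    if (training && rate > 0) {
      cache$D2 <- array((runif(length(H2)) >= rate) / (1 - rate), dim(H2))
      H2 <- H2 * cache$D2
    }
    cache$out_dim2 <- dim(H2)
    Fl <- flatten_fwd(H2)
  } else {
    if (!is.matrix(X)) X <- matrix(X, nrow = 1)
    if (ncol(X) != model$input_shape)
      stop("input dimension ", ncol(X), " does not match model input ",
           model$input_shape)
    Fl <- X
  }
  cache$Fl <- Fl
  A <- Fl
  for (i in seq_along(model$head$hidden_units)) {
    Z <- sweep(A %*% params[[paste0("Wh", i)]], 2, params[[paste0("bh", i)]], "+")
    cache[[paste0("Zh", i, "pos")]] <- (Z > 0)
    cache[[paste0("Ah", i, "_in")]] <- A
    A <- pmax(Z, 0)
  }
  cache$A_last <- A
  logits <- sweep(A %*% params$Wout, 2, params$bout, "+")
  cache$probs <- softmax_rows(logits)
  cache
}

# Backward pass: returns gradient list matching params. Yhot: N x n_classes.
# Requires a cache produced with training=TRUE.
nn_backward <- function(model, cache, Yhot, params = model$params) {
  g <- list()
  N <- nrow(Yhot)
  dZ <- (cache$probs - Yhot) / N
  g$Wout <- crossprod(cache$A_last, dZ)
  g$bout <- colSums(dZ)
  dA <- tcrossprod(dZ, params$Wout)
  for (i in rev(seq_along(model$head$hidden_units))) {
    dZh <- dA * cache[[paste0("Zh", i, "pos")]]
    g[[paste0("Wh", i)]] <- crossprod(cache[[paste0("Ah", i, "_in")]], dZh)
    g[[paste0("bh", i)]] <- colSums(dZh)
    dA <- tcrossprod(dZh, params[[paste0("Wh", i)]])
  }
  if (model$type == "cnn") {
    dH2 <- flatten_bwd(dA, cache$out_dim2)
    if (!is.null(cache$D2)) dH2 <- dH2 * cache$D2
    dZ2 <- maxpool_bwd(cache$P2, dH2) * cache$Z2pos
    bw2 <- conv2d_bwd(cache$M2, params$W2, dZ2, cache$in_dim2)
    g$W2 <- bw2$dW; g$b2 <- bw2$db
    dH1 <- bw2$dX
    if (!is.null(cache$D1)) dH1 <- dH1 * cache$D1
    dZ1 <- maxpool_bwd(cache$P1, dH1) * cache$Z1pos
    bw1 <- conv2d_bwd(cache$M1, params$W1, dZ1, cache$in_dim1,
                      need_dx = FALSE)
    g$W1 <- bw1$dW; g$b1 <- bw1$db
  }
  g
}

# Inference in batches of `chunk` examples: keeps the im2col working set
# small. Returns probs and, if keep_features, the flatten-stage matrix.
nn_infer <- function(model, X, params = model$params, chunk = 64L,
                     keep_features = FALSE) {
  N <- n_examples(X)
  probs <- matrix(0, N, model$n_classes)
  feats <- if (keep_features) matrix(0, N, model$flatten_length) else NULL
  at <- 1L
  while (at <= N) {
    idx <- at:min(at + chunk - 1L, N)
    cache <- nn_forward(model, slice_examples(X, idx), params = params)
    probs[idx, ] <- cache$probs
    if (keep_features) feats[idx, ] <- cache$Fl
    at <- at + chunk
  }
  list(probs = probs, features = feats)
}

cross_entropy <- function(probs, Yhot) {
  -mean(log(pmax(rowSums(probs * Yhot), 1e-12)))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}
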