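# Minimal dense/convolutional network engine used by the frame classifier.
# Tensors are numeric arrays with dim (H, W, C, N); the heavy lifting
# (patch unrolling, scatter-add, warping) is compiled, everything else is
# BLAS matrix products, so the engine stays fast enough for desk-scale
# training on one CPU.

nn_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L,
                    weight_standardization = FALSE) {
  fan_in <- kh * kw * cin
  W <- array(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
             dim = c(kh, kw, cin, cout))
  list(type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
       stride = as.integer(stride), pad = as.integer(pad),
       ws = weight_standardization,
       params = list(W = W, b = numeric(cout)))
}

nn_group_norm <- function(channels, groups = 4L, eps = 1e-5) {
  stopifnot(channels %% groups == 0)
  list(type = "gn", channels = channels, groups = as.integer(groups),
       eps = eps, params = list(gamma = rep(1, channels),
                                beta = numeric(channels)))
}

nn_batch_norm <- function(channels, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", channels = channels, eps = eps, momentum = momentum,
       params = list(gamma = rep(1, channels), beta = numeric(channels)),
       state = list(mean = numeric(channels), var = rep(1, channels)))
}

nn_relu <- function() list(type = "relu", params = list())

nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), params = list())
}

nn_gap <- function() list(type = "gap", params = list())

nn_linear <- function(din, dout) {
  W <- matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout)
  list(type = "linear", din = din, dout = dout,
       params = list(W = W, b = numeric(dout)))
}

# Pre-activation residual bottleneck (v2 ordering: norm-relu-conv x3, with
# an optional projection shortcut taken from the pre-activated input).
nn_resblock <- function(cin, cmid, cout, stride = 1L, groups = 4L,
                        weight_standardization = TRUE) {
  proj <- if (cin != cout || stride != 1L)
    nn_conv(1L, 1L, cin, cout, stride = stride,
            weight_standardization = weight_standardization)
  else NULL
  list(type = "resblock",
       pre = nn_group_norm(cin, groups),
       conv1 = nn_conv(1L, 1L, cin, cmid,
                       weight_standardization = weight_standardization),
       n2 = nn_group_norm(cmid, groups),
       conv2 = nn_conv(3L, 3L, cmid, cmid, stride = stride, pad = 1L,
                       weight_standardization = weight_standardization),
       n3 = nn_group_norm(cmid, groups),
       conv3 = nn_conv(1L, 1L, cmid, cout,
                       weight_standardization = weight_standardization),
       proj = proj, params = list())
}

## ---- forward -----------------------------------------------------------

conv_out_dim <- function(H, k, stride, pad) (H + 2L * pad - k) %/% stride + 1L

standardize_filters <- function(Wmat, eps = 1e-8) {
  mu <- colMeans(Wmat)
  Wc <- sweep(Wmat, 2, mu)
  sd <- sqrt(colMeans(Wc^2) + eps)
  list(What = sweep(Wc, 2, sd, "/"), sd = sd)
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  Ho <- conv_out_dim(H, layer$kh, layer$stride, layer$pad)
  Wo <- conv_out_dim(W, layer$kw, layer$stride, layer$pad)
  Wmat <- matrix(layer$params$W, layer$kh * layer$kw * Cin, layer$cout)
  ws <- NULL
  if (layer$ws) {
    ws <- standardize_filters(Wmat)
    Wmat <- ws$What
  }
  cols <- im2col_cpp(x, H, W, Cin, N, layer$kh, layer$kw,
                     layer$stride, layer$pad)
  out <- crossprod(Wmat, cols) + layer$params$b
  y <- chwn_to_hwcn_cpp(out, Ho, Wo, layer$cout, N)
  dim(y) <- c(Ho, Wo, layer$cout, N)
  list(out = y, cache = list(cols = cols, dims = d, Ho = Ho, Wo = Wo,
                             Wmat = Wmat, ws = ws))
}

conv_backward <- function(layer, cache, dout) {
  d <- cache$dims
  N <- d[4]
  dmat <- hwcn_to_chwn_cpp(dout, cache$Ho, cache$Wo, layer$cout, N)
  dim(dmat) <- c(layer$cout, cache$Ho * cache$Wo * N)
  db <- rowSums(dmat)
  dWmat <- tcrossprod(cache$cols, dmat)
  if (layer$ws) {
    What <- cache$Wmat
    dWmat <- sweep(dWmat, 2, colMeans(dWmat)) -
      sweep(What, 2, colMeans(dWmat * What), "*")
    dWmat <- sweep(dWmat, 2, cache$ws$sd, "/")
  }
  dcols <- cache$Wmat %*% dmat
  dx <- col2im_cpp(dcols, d[1], d[2], d[3], N, layer$kh, layer$kw,
                   layer$stride, layer$pad)
  dim(dx) <- d
  dW <- array(dWmat, dim = dim(layer$params$W))
  list(dx = dx, grads = list(W = dW, b = db))
}

gn_forward <- function(layer, x) {
  d <- dim(x)
  f <- gn_forward_cpp(x, d[1] * d[2], d[3], layer$groups, d[4],
                      layer$params$gamma, layer$params$beta, layer$eps)
  y <- f$y
  dim(y) <- d
  list(out = y, cache = list(xhat = f$xhat, sd = f$sd, dims = d))
}

gn_backward <- function(layer, cache, dout) {
  d <- cache$dims
  b <- gn_backward_cpp(dout, cache$xhat, cache$sd, layer$params$gamma,
                       d[1] * d[2], d[3], layer$groups, d[4])
  dx <- b$dx
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = b$dgamma, beta = b$dbeta))
}

bn_forward <- function(layer, x, train) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(x, H * W, C * N)
  if (train) {
    percn <- matrix(colMeans(xm), C, N)
    mu <- rowMeans(percn)
    cent <- sweep(xm, 2, rep(mu, times = N))
    v <- rowMeans(matrix(colMeans(cent^2), C, N))
  } else {
    mu <- layer$state$mean
    v <- layer$state$var
    cent <- sweep(xm, 2, rep(mu, times = N))
  }
  sd <- sqrt(v + layer$eps)
  xhat <- sweep(cent, 2, rep(sd, times = N), "/")
  y <- sweep(xhat, 2, rep(layer$params$gamma, times = N), "*") +
    matrix(rep(rep(layer$params$beta, times = N), each = H * W), H * W)
  dim(y) <- d
  state <- layer$state
  if (train) {
    state$mean <- (1 - layer$momentum) * state$mean + layer$momentum * mu
    state$var <- (1 - layer$momentum) * state$var + layer$momentum * v
  }
  list(out = y, cache = list(xhat = xhat, sd = sd, dims = d), state = state)
}

bn_backward <- function(layer, cache, dout) {
  d <- cache$dims
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  dm <- matrix(dout, H * W, C * N)
  xhat <- cache$xhat
  dgamma <- rowSums(matrix(colSums(dm * xhat), C, N))
  dbeta <- rowSums(matrix(colSums(dm), C, N))
  dxhat <- sweep(dm, 2, rep(layer$params$gamma, times = N), "*")
  mu1 <- rowMeans(matrix(colMeans(dxhat), C, N))
  mu2 <- rowMeans(matrix(colMeans(dxhat * xhat), C, N))
  dx <- sweep(dxhat, 2, rep(mu1, times = N)) -
    sweep(xhat, 2, rep(mu2, times = N), "*")
  dx <- sweep(dx, 2, rep(cache$sd, times = N), "/")
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

maxpool_forward <- function(layer, x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- layer$k
  Ho <- conv_out_dim(H, k, layer$stride, layer$pad)
  Wo <- conv_out_dim(W, k, layer$stride, layer$pad)
  # pad with -Inf surrogate: use im2col (zero pad) but offset so zeros never win
  off <- max(abs(x)) + 1
  cols <- im2col_cpp(x + off, H, W, C, N, k, k, layer$stride, layer$pad)
  a <- array(cols, c(k * k, C, Ho * Wo * N))
  mx <- apply(a, c(2, 3), max)
  amax <- apply(a, c(2, 3), which.max)
  y <- aperm(array(mx - off, c(C, Ho, Wo, N)), c(2, 3, 1, 4))
  list(out = y, cache = list(amax = amax, dims = d, Ho = Ho, Wo = Wo))
}

maxpool_backward <- function(layer, cache, dout) {
  d <- cache$dims
  C <- d[3]; N <- d[4]
  k <- layer$k
  ncols <- cache$Ho * cache$Wo * N
  dmat <- matrix(aperm(dout, c(3, 1, 2, 4)), C, ncols)
  dcols <- matrix(0, k * k * C, ncols)
  rowidx <- as.vector(cache$amax) + k * k * (rep(seq_len(C), ncols) - 1L)
  colidx <- rep(seq_len(ncols), each = C)
  dcols[cbind(rowidx, colidx)] <- as.vector(dmat)
  dx <- col2im_cpp(dcols, d[1], d[2], C, N, k, k, layer$stride, layer$pad)
  dim(dx) <- d
  list(dx = dx, grads = list())
}

gap_forward <- function(layer, x) {
  d <- dim(x)
  feat <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  list(out = feat, cache = list(dims = d))
}

gap_backward <- function(layer, cache, dout) {
  d <- cache$dims
  hw <- d[1] * d[2]
  dx <- matrix(rep(as.vector(dout), each = hw) / hw, hw)
  dim(dx) <- d
  list(dx = dx, grads = list())
}

linear_forward <- function(layer, x) {
  list(out = crossprod(layer$params$W, x) + layer$params$b,
       cache = list(x = x))
}

linear_backward <- function(layer, cache, dout) {
  list(dx = layer$params$W %*% dout,
       grads = list(W = tcrossprod(cache$x, dout), b = rowSums(dout)))
}

layer_forward <- function(layer, x, train) {
  switch(layer$type,
    conv = conv_forward(layer, x),
    gn = gn_forward(layer, x),
    bn = bn_forward(layer, x, train),
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask))
    },
    maxpool = maxpool_forward(layer, x),
    gap = gap_forward(layer, x),
    linear = linear_forward(layer, x),
    resblock = resblock_forward(layer, x, train),
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = conv_backward(layer, cache, dout),
    gn = gn_backward(layer, cache, dout),
    bn = bn_backward(layer, cache, dout),
    relu = list(dx = dout * cache$mask, grads = list()),
    maxpool = maxpool_backward(layer, cache, dout),
    gap = gap_backward(layer, cache, dout),
    linear = linear_backward(layer, cache, dout),
    resblock = resblock_backward(layer, cache, dout),
    stop("unknown layer type: ", layer$type)
  )
}

resblock_sublayers <- c("pre", "conv1", "n2", "conv2", "n3", "conv3")

resblock_forward <- function(layer, x, train) {
  caches <- list()
  f <- gn_forward(layer$pre, x); caches$pre <- f$cache
  pre <- f$out
  mask0 <- pre > 0
  h <- pre * mask0
  caches$relu0 <- mask0
  if (!is.null(layer$proj)) {
    p <- conv_forward(layer$proj, h)
    caches$proj <- p$cache
    skip <- p$out
  } else skip <- x
  f <- conv_forward(layer$conv1, h); caches$conv1 <- f$cache
  f2 <- gn_forward(layer$n2, f$out); caches$n2 <- f2$cache
  mask1 <- f2$out > 0; caches$relu1 <- mask1
  f3 <- conv_forward(layer$conv2, f2$out * mask1); caches$conv2 <- f3$cache
  f4 <- gn_forward(layer$n3, f3$out); caches$n3 <- f4$cache
  mask2 <- f4$out > 0; caches$relu2 <- mask2
  f5 <- conv_forward(layer$conv3, f4$out * mask2); caches$conv3 <- f5$cache
  list(out = f5$out + skip, cache = caches)
}

resblock_backward <- function(layer, cache, dout) {
  grads <- list()
  b <- conv_backward(layer$conv3, cache$conv3, dout)
  grads$conv3 <- b$grads
  b2 <- gn_backward(layer$n3, cache$n3, b$dx * cache$relu2)
  grads$n3 <- b2$grads
  b3 <- conv_backward(layer$conv2, cache$conv2, b2$dx)
  grads$conv2 <- b3$grads
  b4 <- gn_backward(layer$n2, cache$n2, b3$dx * cache$relu1)
  grads$n2 <- b4$grads
  b5 <- conv_backward(layer$conv1, cache$conv1, b4$dx)
  grads$conv1 <- b5$grads
  dh <- b5$dx
  dskip_x <- NULL
  if (!is.null(layer$proj)) {
    bp <- conv_backward(layer$proj, cache$proj, dout)
    grads$proj <- bp$grads
    dh <- dh + bp$dx
  } else dskip_x <- dout
  dpre <- dh * cache$relu0
  b6 <- gn_backward(layer$pre, cache$pre, dpre)
  grads$pre <- b6$grads
  dx <- b6$dx
  if (!is.null(dskip_x)) dx <- dx + dskip_x
  list(dx = dx, grads = grads)
}

## ---- whole-network pass ------------------------------------------------

# Returns logits (K x N), the penultimate (post-GAP) features (D x N) and
# per-layer caches for the backward pass.
nn_forward <- function(model, x, train = FALSE) {
  caches <- vector("list", length(model$layers))
  features <- NULL
  for (i in seq_along(model$layers)) {
    layer <- model$layers[[i]]
    f <- layer_forward(layer, x, train)
    caches[[i]] <- f$cache
    if (!is.null(f$state)) model$layers[[i]]$state <- f$state
    x <- f$out
    if (layer$type == "gap") features <- x
  }
  list(logits = x, features = features, caches = caches, model = model)
}

nn_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  dx <- dlogits
  for (i in rev(seq_along(model$layers))) {
    b <- layer_backward(model$layers[[i]], caches[[i]], dx)
    grads[[i]] <- b$grads
    dx <- b$dx
  }
  grads
}

# Mean softmax cross-entropy over columns of logits (K x N); labels in 1..K.
softmax_xent <- function(logits, labels) {
  K <- nrow(logits); N <- ncol(logits)
  mx <- apply(logits, 2, max)
  z <- sweep(logits, 2, mx)
  ez <- exp(z)
  sm <- sweep(ez, 2, colSums(ez), "/")
  idx <- cbind(labels, seq_len(N))
  picked <- sm[idx]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- sm
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / N
  list(loss = loss, dlogits = dlogits,
       correct = max.col(t(logits)) == labels)
}

## ---- parameter traversal & AdamW --------------------------------------

# Flattens the (possibly nested) parameter tree into a list of numeric
# arrays addressed by [layer index][sub path][param name].
param_paths <- function(model) {
  paths <- list()
  for (i in seq_along(model$layers)) {
    layer <- model$layers[[i]]
    if (layer$type == "resblock") {
      subs <- c(resblock_sublayers, if (!is.null(layer$proj)) "proj")
      for (s in subs)
        for (p in names(layer[[s]]$params))
          paths[[length(paths) + 1L]] <- list(i = i, sub = s, p = p)
    } else {
      for (p in names(layer$params))
        paths[[length(paths) + 1L]] <- list(i = i, sub = NULL, p = p)
    }
  }
  paths
}

get_param <- function(model, pa) {
  if (is.null(pa$sub)) model$layers[[pa$i]]$params[[pa$p]]
  else model$layers[[pa$i]][[pa$sub]]$params[[pa$p]]
}

set_param <- function(model, pa, value) {
  if (is.null(pa$sub)) model$layers[[pa$i]]$params[[pa$p]] <- value
  else model$layers[[pa$i]][[pa$sub]]$params[[pa$p]] <- value
  model
}

get_grad <- function(grads, pa) {
  if (is.null(pa$sub)) grads[[pa$i]][[pa$p]]
  else grads[[pa$i]][[pa$sub]][[pa$p]]
}

adamw_init <- function(model) {
  paths <- param_paths(model)
  list(paths = paths, t = 0L,
       m = lapply(paths, function(pa) get_param(model, pa) * 0),
       v = lapply(paths, function(pa) get_param(model, pa) * 0))
}

# Decoupled weight decay (applied to weights, not to norm scales/biases).
adamw_step <- function(model, grads, opt, lr, betas = c(0, 0.999),
                       eps = 1e-8, weight_decay = 0.01) {
  opt$t <- opt$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  for (k in seq_along(opt$paths)) {
    pa <- opt$paths[[k]]
    g <- get_grad(grads, pa)
    if (is.null(g)) next
    opt$m[[k]] <- b1 * opt$m[[k]] + (1 - b1) * g
    opt$v[[k]] <- b2 * opt$v[[k]] + (1 - b2) * g^2
    mhat <- opt$m[[k]] / (1 - b1^opt$t)
    vhat <- opt$v[[k]] / (1 - b2^opt$t)
    p <- get_param(model, pa)
    decay <- if (pa$p %in% c("W")) weight_decay else 0
    p <- p - lr * (mhat / (sqrt(vhat) + eps) + decay * p)
    model <- set_param(model, pa, p)
  }
  list(model = model, opt = opt)
}
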