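# Primitive differentiable layers for the residual feature encoder.
# Activations are 5-D arrays laid out (channels, depth, height, width, batch);
# fully connected activations are matrices (features x batch).

# Convolutions here are always followed by batch normalization, which absorbs
# any additive offset, so they carry no bias term (standard ResNet practice;
# a bias would receive an identically zero gradient through BN).
# Kernel, stride and pad are per axis (depth, height, width): an axis that has
# collapsed to size 1 gets a length-1 kernel so no tap sees only padding.
conv_layer <- function(cin, cout, k, stride, pad) {
  k <- rep(as.integer(k), length.out = 3L)
  stride <- rep(as.integer(stride), length.out = 3L)
  pad <- rep(as.integer(pad), length.out = 3L)
  fan_in <- cin * prod(k)
  w <- array(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
             dim = c(cout, cin, k))
  list(w = w, stride = stride, pad = pad, k = k)
}

conv_fwd <- function(layer, x) {
  conv3d_forward_cpp(x, layer$w, numeric(dim(layer$w)[1L]),
                     layer$stride, layer$pad)
}

conv_bwd <- function(layer, x, dy) {
  conv3d_backward_cpp(x, layer$w, dy, layer$stride, layer$pad)
}

bn_layer <- function(c, momentum = 0.1, eps = 1e-5) {
  list(gamma = rep(1, c), beta = numeric(c), rmean = numeric(c),
       rvar = rep(1, c), momentum = momentum, eps = eps)
}

# Batch normalization over all non-channel axes. Training mode uses biased
# batch statistics (and updates running estimates); evaluation mode uses the
# running estimates, making the map deterministic.
bn_fwd <- function(layer, x, training) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1L])
  if (training) {
    mu <- rowMeans(m)
    v <- rowMeans(m * m) - mu * mu
    v <- pmax(v, 0)
    mom <- layer$momentum
    layer$rmean <- (1 - mom) * layer$rmean + mom * mu
    layer$rvar <- (1 - mom) * layer$rvar + mom * v
  } else {
    mu <- layer$rmean
    v <- layer$rvar
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- (m - mu) * invstd
  y <- layer$gamma * xhat + layer$beta
  dim(y) <- d
  list(y = y, layer = layer,
       cache = if (training) list(xhat = xhat, invstd = invstd, dims = d)
               else list(xhat = xhat, invstd = invstd, dims = d, frozen = TRUE))
}

bn_bwd <- function(layer, cache, dy) {
  dym <- matrix(dy, nrow = dim(dy)[1L])
  xhat <- cache$xhat
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  if (isTRUE(cache$frozen)) {
    dx <- layer$gamma * cache$invstd * dym
  } else {
    dx <- layer$gamma * cache$invstd *
      (dym - rowMeans(dym) - xhat * rowMeans(dym * xhat))
  }
  dim(dx) <- cache$dims
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(y, dy) {
  dy[y <= 0] <- 0
  dy
}

# Max pooling with kernel 2 / stride 2 on every spatial axis of size >= 2
# (axes of size 1 are left untouched).
pool_kernel <- function(xdim) {
  as.integer(ifelse(xdim[2:4] >= 2L, 2L, 1L))
}

pool_fwd <- function(x) {
  k <- pool_kernel(dim(x))
  res <- maxpool3d_forward_cpp(x, k)
  list(y = res$y, argmax = res$argmax, xdim = dim(x))
}

pool_bwd <- function(cache, dy) {
  maxpool3d_backward_cpp(dy, cache$argmax, as.integer(cache$xdim))
}

# Global average pooling (C, D, H, W, N) -> (C, N).
gpool_fwd <- function(x) {
  d <- dim(x)
  s <- prod(d[2:4])
  arr <- array(x, c(d[1L], s, d[5L]))
  y <- colSums(aperm(arr, c(2L, 1L, 3L))) / s
  dim(y) <- c(d[1L], d[5L])
  list(y = y, xdim = d)
}

gpool_bwd <- function(cache, dy) {
  d <- cache$xdim
  s <- prod(d[2:4])
  dx <- aperm(array(dy / s, c(d[1L], d[5L], s)), c(1L, 3L, 2L))
  dim(dx) <- d
  dx
}

linear_layer <- function(nin, nout) {
  list(w = matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin),
       b = numeric(nout))
}

linear_fwd <- function(layer, x) {
  layer$w %*% x + layer$b
}

linear_bwd <- function(layer, x, dy) {
  list(dx = crossprod(layer$w, dy), dw = tcrossprod(dy, x), db = rowSums(dy))
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(cache, dy) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}
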