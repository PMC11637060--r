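# Network layer primitives operating on (H, W, C) arrays, with forward and
# backward passes. Convolution, pooling and resizing run through compiled
# kernels; activations and batch normalization are vectorized in R.
# A batch is a list of (H, W, C) arrays.

as_cube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

conv_init <- function(kh, kw, cin, cout) {
  fan_in <- cin * kh * kw
  fan_out <- cout * kh * kw
  lim <- sqrt(6 / (fan_in + fan_out))
  list(W = matrix(runif(cout * fan_in, -lim, lim), cout, fan_in),
       b = numeric(cout))
}

conv_fwd <- function(x, p, cfg) {
  .conv2d_forward(as_cube(x), p$W, p$b, cfg$kh, cfg$kw, cfg$sh, cfg$sw,
                  cfg$ph, cfg$pw)
}

conv_bwd <- function(x, p, gy, cfg) {
  .conv2d_backward(as_cube(x), p$W, as_cube(gy), cfg$kh, cfg$kw, cfg$sh,
                   cfg$sw, cfg$ph, cfg$pw)
}

lrelu_fwd <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  list(y = x, mask = neg)
}

lrelu_bwd <- function(gy, mask, slope) {
  gy[mask] <- gy[mask] * slope
  gy
}

# batch normalization over a batch (list of (H,W,C) arrays), per channel;
# per-channel arithmetic is vectorized by collapsing (H,W) to matrix rows
bn_fwd <- function(xs, gamma, beta, eps, training, rmean, rvar) {
  d <- dim(xs[[1]])
  C <- d[3]; n_per <- d[1] * d[2]
  xm <- lapply(xs, function(x) matrix(x, n_per, C))
  if (training) {
    n <- n_per * length(xs)
    s <- Reduce(`+`, lapply(xm, colSums))
    ss <- Reduce(`+`, lapply(xm, function(m) colSums(m * m)))
    mu <- s / n
    v <- pmax(ss / n - mu^2, 0)
  } else {
    mu <- rmean; v <- rvar
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- lapply(xm, function(m) {
    m <- (m - rep(mu, each = n_per)) * rep(inv_sd, each = n_per)
    m
  })
  ys <- lapply(xhat, function(m) {
    y <- m * rep(gamma, each = n_per) + rep(beta, each = n_per)
    dim(y) <- d
    y
  })
  list(y = ys, xhat = xhat, mu = mu, var = v, inv_sd = inv_sd, dim = d)
}

bn_bwd <- function(gys, cache, gamma) {
  d <- cache$dim
  C <- d[3]; n_per <- d[1] * d[2]
  n <- n_per * length(gys)
  gm <- lapply(gys, function(g) matrix(g, n_per, C))
  dbeta <- Reduce(`+`, lapply(gm, colSums))
  dgamma <- Reduce(`+`, Map(function(g, xh) colSums(g * xh), gm, cache$xhat))
  mean_dy <- dbeta / n
  mean_dy_xhat <- dgamma / n
  coef <- gamma * cache$inv_sd
  gxs <- Map(function(g, xh) {
    gx <- (g - rep(mean_dy, each = n_per) -
             xh * rep(mean_dy_xhat, each = n_per)) *
      rep(coef, each = n_per)
    dim(gx) <- d
    gx
  }, gm, cache$xhat)
  list(gx = gxs, dgamma = dgamma, dbeta = dbeta)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:2] == db[1:2]))
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}
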