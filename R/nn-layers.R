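# Minimal layer primitives with explicit forward/backward passes. Activations
# are 4-D arrays [H, W, C, N]; convolution and pooling run through the compiled
# im2col/GEMM kernels, batch-norm and the rest are vectorized R.

conv_fwd <- function(x, w, b) cn_conv_fwd(x, w, b)

conv_bwd <- function(x, w, dy) cn_conv_bwd(x, w, dy)

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

relu_bwd <- function(dy, mask) dy * mask

pool_fwd <- function(x) {
  out <- cn_pool_fwd(x)
  # C indices are 0-based; keep them so, pool_bwd consumes them directly
  list(y = out$y, idx = out$idx, in_dim = dim(x))
}

pool_bwd <- function(dy, cache) {
  dx <- cn_pool_bwd(cache$idx, dy, as.integer(cache$in_dim))
  dim(dx) <- cache$in_dim
  dx
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(y = x, mask = NULL))
  }
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(dy, mask) if (is.null(mask)) dy else dy * mask

bn_eps <- 1e-5

# per-channel sums of a [H, W, C, N] array: reshape to (HW) x (C*N), column
# sums, then row sums over the C x N matrix
channel_sums <- function(x, d) {
  cs <- .colSums(x, d[1] * d[2], d[3] * d[4])
  .rowSums(cs, d[3], d[4])
}

# per-channel vector expanded to recycle over a [H, W, C, N] array: length
# HW*C recycles across images
channel_expand <- function(v, d) rep(v, each = d[1] * d[2])

# spatial batch normalization over (H, W, N) per channel
bn_fwd <- function(x, gamma, beta, state, training, momentum = 0.9) {
  d <- dim(x)
  n <- d[1] * d[2] * d[4]
  if (training) {
    m <- channel_sums(x, d) / n
    v <- channel_sums(x^2, d) / n - m^2
    v <- pmax(v, 0)
    state$mean <- momentum * state$mean + (1 - momentum) * m
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    m <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + bn_eps)
  xhat <- x * channel_expand(invstd, d) - channel_expand(m * invstd, d)
  y <- xhat * channel_expand(gamma, d) + channel_expand(beta, d)
  dim(y) <- d
  dim(xhat) <- d
  list(y = y, xhat = xhat, invstd = invstd, state = state)
}

bn_bwd <- function(dy, cache, gamma) {
  d <- dim(dy)
  n <- d[1] * d[2] * d[4]
  xhat <- cache$xhat
  dgamma <- channel_sums(dy * xhat, d)
  dbeta <- channel_sums(dy, d)
  # dxhat = dy * gamma; dx = invstd/n * (n*dxhat - sum(dxhat) - xhat*sum(dxhat*xhat))
  g <- channel_expand(gamma, d)
  dx <- (dy * g) * n - channel_expand(gamma * dbeta, d) -
    xhat * channel_expand(gamma * dgamma, d)
  dx <- dx * channel_expand(cache$invstd / n, d)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# squash map: v -> (|v|^2 / (1 + |v|^2)) * v / |v|; its norm u^2/(1+u^2) < 1
squash_norm <- function(u) u^2 / (1 + u^2)
squash_norm_grad <- function(u) 2 * u / (1 + u^2)^2

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout) * sqrt(2 / (kh * kw * cin)), c(kh, kw, cin, cout))
}

# elementwise map over two parallel nested parameter lists
tree_map2 <- function(f, a, b) {
  if (is.list(a))

    return(mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    return(lapply(a, tree_map, f = f))
  }
  f(a)
}

adam_init <- function(params) {
  list(
    m = tree_map(function(p) p * 0, params),
    v = tree_map(function(p) p * 0, params),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps), state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
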