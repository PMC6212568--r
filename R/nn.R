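# Internal neural-network primitives: dense layers, batch-normalised
# linear blocks LB(x) = ReLU(BN(Wx + b)), exact backward passes, and Adam.
# All matrices are row-per-sample. Written in base R matrix code; the
# networks here are small enough that BLAS-backed matmuls dominate.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# column-wise broadcast helpers: apply v[j] across column j
.rowmult <- function(X, v) X * rep(v, each = nrow(X))
.rowadd <- function(X, v) X + rep(v, each = nrow(X))

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  out <- x
  lo <- x <= 30
  out[lo] <- log1p(exp(x[lo]))
  out
}

# binary cross-entropy from logits, elementwise: log(1+e^o) - t*o
.bce_logits <- function(o, t) .softplus(o) - t * o

.init_dense <- function(d_in, d_out) {
  # fan-in scaled normal ("He") initialisation; biases zero
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

.init_lb <- function(d_in, d_out) {
  c(.init_dense(d_in, d_out),
    list(gamma = rep(1, d_out), beta = numeric(d_out)))
}

.init_bn_stats <- function(d_out) list(mean = numeric(d_out), var = rep(1, d_out))

# ---- linear block forward/backward ----------------------------------------

# activation: "relu" or "sigmoid" (the discriminator's output block swaps
# the rectifier for a sigmoid but keeps the batch-norm)
.lb_forward <- function(p, X, stats, train, activation = "relu") {
  A <- .rowadd(X %*% p$W, p$b)
  n <- nrow(A)
  if (train) {
    m <- colMeans(A)
    v <- pmax(colMeans(A * A) - m * m, 0)
    stats$mean <- (1 - .BN_MOMENTUM) * stats$mean + .BN_MOMENTUM * m
    stats$var <- (1 - .BN_MOMENTUM) * stats$var + .BN_MOMENTUM * v
  } else {
    m <- stats$mean
    v <- stats$var
  }
  inv <- 1 / sqrt(v + .BN_EPS)
  xhat <- .rowmult(.rowadd(A, -m), inv)
  bn <- .rowadd(.rowmult(xhat, p$gamma), p$beta)
  H <- switch(activation, relu = pmax(bn, 0), sigmoid = .sigmoid(bn),
              linear = bn)
  list(out = H,
       cache = list(X = X, xhat = xhat, inv = inv, bn = bn, act = activation),
       stats = stats)
}

.lb_backward <- function(p, cache, dH) {
  dBn <- switch(cache$act,
                relu = dH * (cache$bn > 0),
                sigmoid = dH * .sigmoid(cache$bn) * (1 - .sigmoid(cache$bn)),
                linear = dH)  # caller supplies the gradient at the BN output
  n <- nrow(dBn)
  dgamma <- colSums(dBn * cache$xhat)
  dbeta <- colSums(dBn)
  dxhat <- .rowmult(dBn, p$gamma)
  s1 <- colSums(dxhat) / n
  s2 <- colSums(dxhat * cache$xhat) / n
  dA <- .rowmult(dxhat - .rowadd(.rowmult(cache$xhat, s2), s1), cache$inv)
  list(grad = list(W = crossprod(cache$X, dA), b = colSums(dA),
                   gamma = dgamma, beta = dbeta),
       dX = tcrossprod(dA, p$W))
}

# ---- stacks of linear blocks ----------------------------------------------

.stack_forward <- function(blocks, X, stats, train, last_activation = "relu") {
  caches <- vector("list", length(blocks))
  H <- X
  for (i in seq_along(blocks)) {
    act <- if (i == length(blocks)) last_activation else "relu"
    fw <- .lb_forward(blocks[[i]], H, stats[[i]], train, act)
    H <- fw$out
    caches[[i]] <- fw$cache
    stats[[i]] <- fw$stats
  }
  list(out = H, caches = caches, stats = stats)
}

.stack_backward <- function(blocks, caches, dH) {
  grads <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    bw <- .lb_backward(blocks[[i]], caches[[i]], dH)
    grads[[i]] <- bw$grad
    dH <- bw$dX
  }
  list(grads = grads, dX = dH)
}

# ---- parameter-tree utilities and Adam ------------------------------------

.tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1L]]
  if (is.list(t1)) {
    out <- vector("list", length(t1))
    names(out) <- names(t1)
    for (i in seq_along(t1))
      out[[i]] <- do.call(.tree_map, c(list(f), lapply(trees, `[[`, i)))
    out
  } else {
    do.call(f, trees)
  }
}

.zeros_like <- function(p) .tree_map(function(x) x * 0, p)

.adam_init <- function(params) list(m = .zeros_like(params), v = .zeros_like(params), t = 0L)

# Adam with both moment-decay constants configurable (the models here use
# beta1 = beta2 = 0.9)
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.9,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- .tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- .tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                      params, state$m, state$v)
  list(params = params, state = state)
}
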