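# Internal layer operations for the convolutional autoencoder.
# Batches are 3-d arrays (length, channels, batch); the compiled conv /
# transposed-conv kernels in src/convnet.cpp do the heavy lifting and the
# cheap elementwise pieces (batch norm, ReLU, dropout, loss) live here.

relu_fw <- function(x) x * (x > 0)
relu_bw <- function(dy, x) dy * (x > 0)

sigmoid <- function(z) 1 / (1 + exp(-z))

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# Batch normalization over (length x batch) per channel.
bn_fw <- function(x, gamma, beta, run_mean, run_var, training) {
  d <- dim(x)
  out <- x
  cache <- NULL
  if (training) {
    mu <- numeric(d[2]); va <- numeric(d[2])
    xhat <- x
    for (f in seq_len(d[2])) {
      slab <- x[, f, , drop = FALSE]
      mu[f] <- mean(slab)
      va[f] <- mean((slab - mu[f])^2)
      xhat[, f, ] <- (slab - mu[f]) / sqrt(va[f] + BN_EPS)
      out[, f, ] <- gamma[f] * xhat[, f, , drop = FALSE] + beta[f]
    }
    run_mean <- BN_MOMENTUM * run_mean + (1 - BN_MOMENTUM) * mu
    run_var <- BN_MOMENTUM * run_var + (1 - BN_MOMENTUM) * va
    cache <- list(xhat = xhat, mu = mu, va = va)
  } else {
    for (f in seq_len(d[2])) {
      out[, f, ] <- gamma[f] *
        (x[, f, , drop = FALSE] - run_mean[f]) / sqrt(run_var[f] + BN_EPS) +
        beta[f]
    }
  }
  list(out = out, cache = cache, run_mean = run_mean, run_var = run_var)
}

bn_bw <- function(dy, cache, gamma) {
  d <- dim(dy)
  n <- d[1] * d[3]
  dx <- dy
  dgamma <- numeric(d[2]); dbeta <- numeric(d[2])
  for (f in seq_len(d[2])) {
    dyf <- dy[, f, , drop = FALSE]
    xhat <- cache$xhat[, f, , drop = FALSE]
    ivar <- 1 / sqrt(cache$va[f] + BN_EPS)
    dgamma[f] <- sum(dyf * xhat)
    dbeta[f] <- sum(dyf)
    dxhat <- dyf * gamma[f]
    dx[, f, ] <- ivar / n *
      (n * dxhat - sum(dxhat) - xhat * sum(dxhat * xhat))
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Weighted binary cross-entropy on sigmoid outputs; returns the mean loss
# and the gradient with respect to the pre-sigmoid logits.
bce_loss <- function(p, y, pos_weight) {
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  n <- length(p)
  loss <- -sum(pos_weight * y * log(pc) + (1 - y) * log(1 - pc)) / n
  dz <- ((1 - y) * p - pos_weight * y * (1 - p)) / n
  list(loss = loss, dz = dz)
}

# One Adam step for a single tensor; state carries m, v, t.
adam_step <- function(param, grad, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) {
    state <- list(m = param * 0, v = param * 0, t = 0)
  }
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Full forward pass. Returns sigmoid output (L x 1 x B) and, when
# `keep_cache`, everything the backward pass needs.
nn_forward <- function(params, x, training = FALSE, dropout_rate = 0,
                       keep_cache = FALSE) {
  h <- x
  caches <- vector("list", length(params$layers))
  for (li in seq_along(params$layers)) {
    lay <- params$layers[[li]]
    cache <- list(x_in = if (keep_cache) h else NULL)
    if (lay$type == "conv") {
      z <- nn_conv1d_fw(h, lay$W, lay$b, lay$stride, lay$pad)
    } else {
      z <- nn_tconv1d_fw(h, lay$W, lay$b, lay$stride, lay$pad)
    }
    if (!is.null(lay$gamma)) {
      bn <- bn_fw(z, lay$gamma, lay$beta, lay$run_mean, lay$run_var,
                  training)
      if (training) {
        params$layers[[li]]$run_mean <- bn$run_mean
        params$layers[[li]]$run_var <- bn$run_var
      }
      cache$z <- if (keep_cache) z else NULL
      cache$bn <- bn$cache
      z <- bn$out
    }
    if (lay$activation == "relu") {
      cache$pre_act <- if (keep_cache) z else NULL
      z <- relu_fw(z)
    } else if (lay$activation == "sigmoid") {
      z <- sigmoid(z)
    }
    if (isTRUE(lay$dropout_after) && training && dropout_rate > 0) {
      keep <- array(stats::runif(length(z)) >= dropout_rate, dim = dim(z))
      z <- z * keep / (1 - dropout_rate)
      cache$drop_mask <- keep
    }
    caches[[li]] <- cache
    h <- z
  }
  list(out = h, caches = caches, params = params)
}

# Backward pass from the loss gradient w.r.t. the logits (dz of bce_loss;
# the sigmoid derivative is already folded in). Returns gradients parallel
# to params$layers.
nn_backward <- function(params, caches, dz, dropout_rate = 0) {
  grads <- vector("list", length(params$layers))
  dy <- dz
  for (li in rev(seq_along(params$layers))) {
    lay <- params$layers[[li]]
    cache <- caches[[li]]
    if (!is.null(cache$drop_mask)) {
      dy <- dy * cache$drop_mask / (1 - dropout_rate)
    }
    if (lay$activation == "relu") {
      dy <- relu_bw(dy, cache$pre_act)
    }
    g <- list()
    if (!is.null(lay$gamma)) {
      bnb <- bn_bw(dy, cache$bn, lay$gamma)
      g$dgamma <- bnb$dgamma
      g$dbeta <- bnb$dbeta
      dy <- bnb$dx
    }
    if (lay$type == "conv") {
      cb <- nn_conv1d_bw(cache$x_in, lay$W, dy, lay$stride, lay$pad)
    } else {
      cb <- nn_tconv1d_bw(cache$x_in, lay$W, dy, lay$stride, lay$pad)
    }
    g$dW <- cb$dW
    g$db <- cb$db
    grads[[li]] <- g
    dy <- cb$dx
  }
  grads
}

# Loss + gradients for one batch; the oracle for the finite-difference
# gradient-check test.
nn_loss_and_grads <- function(params, x, y, pos_weight, dropout_rate = 0) {
  fw <- nn_forward(params, x, training = TRUE, dropout_rate = dropout_rate,
                   keep_cache = TRUE)
  lo <- bce_loss(fw$out, y, pos_weight)
  grads <- nn_backward(fw$params, fw$caches, lo$dz, dropout_rate)
  list(loss = lo$loss, grads = grads, params = fw$params)
}

nn_loss_only <- function(params, x, y, pos_weight) {
  fw <- nn_forward(params, x, training = TRUE, dropout_rate = 0)
  bce_loss(fw$out, y, pos_weight)$loss
}
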