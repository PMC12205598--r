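# Minimal dense neural-network engine used by the desk-scale segmentation and
# embedding models: fully connected layers, ReLU hidden units, sigmoid or
# softmax output, binary/categorical cross-entropy, minibatch SGD with
# momentum and a cosine-annealed learning rate.

nn_init <- function(sizes, seed = 1L) {
  with_stream_seed(seed, {
    n <- length(sizes) - 1L
    W <- vector("list", n); b <- vector("list", n)
    for (i in seq_len(n)) {
      W[[i]] <- matrix(rnorm(sizes[i] * sizes[i + 1], sd = sqrt(2 / sizes[i])),
                       sizes[i], sizes[i + 1])
      b[[i]] <- rep(0, sizes[i + 1])
    }
    list(W = W, b = b, sizes = sizes)
  })
}

nn_forward <- function(par, X, output = c("sigmoid", "softmax")) {
  output <- match.arg(output)
  n <- length(par$W)
  acts <- vector("list", n + 1L)
  acts[[1]] <- X
  for (i in seq_len(n)) {
    Z <- sweep(acts[[i]] %*% par$W[[i]], 2, par$b[[i]], "+")
    if (i < n) Z[Z < 0] <- 0  # ReLU
    else Z <- switch(output,
      sigmoid = 1 / (1 + exp(-Z)),
      softmax = {
        Z <- exp(Z - apply(Z, 1, max))
        Z / rowSums(Z)
      })
    acts[[i + 1]] <- Z
  }
  acts
}

# Gradient of the cross-entropy loss (sigmoid + BCE or softmax + CE share the
# same output delta: prediction minus target).
nn_backward <- function(par, acts, Y) {
  n <- length(par$W)
  m <- nrow(Y)
  delta <- (acts[[n + 1]] - Y) / m
  gW <- vector("list", n); gb <- vector("list", n)
  for (i in n:1) {
    gW[[i]] <- crossprod(acts[[i]], delta)
    gb[[i]] <- colSums(delta)
    if (i > 1) {
      delta <- delta %*% t(par$W[[i]])
      delta[acts[[i]] <= 0] <- 0
    }
  }
  list(W = gW, b = gb)
}

cosine_lr <- function(step, total, lr_init, lr_final) {
  lr_final + 0.5 * (lr_init - lr_final) * (1 + cos(pi * min(step, total) / total))
}

# One momentum-SGD update, in place on the parameter list.
nn_step <- function(par, grad, state, lr, momentum = 0.9) {
  for (i in seq_along(par$W)) {
    state$vW[[i]] <- momentum * state$vW[[i]] - lr * grad$W[[i]]
    state$vb[[i]] <- momentum * state$vb[[i]] - lr * grad$b[[i]]
    par$W[[i]] <- par$W[[i]] + state$vW[[i]]
    par$b[[i]] <- par$b[[i]] + state$vb[[i]]
  }
  list(par = par, state = state)
}

nn_state_init <- function(par) {
  list(vW = lapply(par$W, function(w) w * 0), vb = lapply(par$b, function(b) b * 0))
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

ce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(log(rowSums(p * y) + eps))
}
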