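# Minimal multilayer perceptron with manual backpropagation.
#
# A network is a list with elements W (list of d_prev x d_next weight
# matrices) and b (list of bias vectors). Hidden layers use ReLU; the output
# layer is linear (any squashing is applied by the caller, so that encoder
# mean / log-variance heads and sigmoid decoders share one implementation).

mlp_init <- function(d_in, hidden, d_out, zero_last = FALSE) {
  dims <- c(d_in, hidden, d_out)
  W <- vector("list", length(dims) - 1)
  b <- vector("list", length(dims) - 1)
  for (l in seq_along(W)) {
    a <- sqrt(6 / (dims[l] + dims[l + 1]))
    W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -a, a), dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  if (zero_last) W[[length(W)]][] <- 0
  list(W = W, b = b)
}

# forward pass over a batch X (n x d_in); returns output and the
# activations needed for the backward pass
mlp_forward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    Z <- X %*% net$W[[l]]
    b <- net$b[[l]]
    Z <- Z + matrix(b, nrow(Z), length(b), byrow = TRUE)
    X <- if (l < L) Z * (Z > 0) else Z
    acts[[l + 1]] <- X
  }
  list(out = acts[[L + 1]], acts = acts)
}

# backward pass: dOut is the gradient of the loss w.r.t. the network output
# (n x d_out). Returns parameter gradients and the gradient w.r.t. X.
mlp_backward <- function(net, cache, dOut) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    A <- cache$acts[[l]]
    gW[[l]] <- crossprod(A, delta)
    gb[[l]] <- colSums(delta)
    delta <- tcrossprod(delta, net$W[[l]])
    if (l > 1) delta <- delta * (cache$acts[[l]] > 0)  # ReLU mask
  }
  list(W = gW, b = gb, dX = delta)
}

# --- flat parameter-list helpers (used by the Adam optimizer) ---------------

# Leaf addressing: a nested parameter structure is walked once to record the
# path of every numeric leaf; Adam then loops over the flat leaf list with
# plain vector arithmetic (no recursion in the hot path).
param_paths <- function(x) {
  out <- list()
  walk <- function(node, path) {
    if (is.list(node)) {
      for (i in seq_along(node)) walk(node[[i]], c(path, i))
    } else {
      out[[length(out) + 1]] <<- path
    }
  }
  walk(x, integer())
  out
}

adam_init <- function(params) {
  paths <- param_paths(params)
  leaves <- lapply(paths, function(p) params[[p]] * 0)
  list(m = leaves, v = leaves, t = 0, paths = paths)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  paths <- state$paths
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    g <- grads[[p]]
    m <- beta1 * state$m[[i]] + (1 - beta1) * g
    v <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    state$m[[i]] <- m
    state$v[[i]] <- v
    params[[p]] <- params[[p]] - lr * (m / c1) / (sqrt(v / c2) + eps)
  }
  list(params = params, state = state)
}
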