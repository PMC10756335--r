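# Minimal neural-network primitives with explicit backward passes.
# Convolutions are evaluated as im2col + GEMM so the heavy lifting stays in
# BLAS; index maps are precomputed once per (input shape, kernel, stride).

# Linear index map for valid convolution: rows = output positions,
# cols = kernel-window entries (k*k*cin), values = indices into the input
# array (h x w x cin, column-major).
im2col_index <- function(h, w, cin, k, stride) {
  ho <- (h - k) %/% stride + 1
  wo <- (w - k) %/% stride + 1
  oy <- rep(seq(0, by = stride, length.out = ho), times = wo)
  ox <- rep(seq(0, by = stride, length.out = wo), each = ho)
  base <- oy + ox * h                       # top-left of each window
  ky <- rep(0:(k - 1), times = k * cin)
  kx <- rep(rep(0:(k - 1), each = k), times = cin)
  kc <- rep(0:(cin - 1), each = k * k)
  off <- ky + kx * h + kc * h * w
  idx <- outer(base, off, "+") + 1L
  storage.mode(idx) <- "integer"
  list(idx = idx, ho = ho, wo = wo)
}

im2col <- function(x, map) {
  matrix(x[map$idx], nrow = nrow(map$idx))
}

# Adam with L2 weight decay folded into the gradient. `params`, `grads` and
# the state are parallel named lists of numeric arrays.
adam_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- lr * mhat / (sqrt(vhat) + eps)
    dim(upd) <- dim(params[[nm]])
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

# Glorot-uniform initializer.
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}
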