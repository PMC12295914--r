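# Shared numeric machinery for the four sequence classifiers: seeded
# initialisation, embedding lookup, Adam, binary cross-entropy.
# Everything operates on plain double matrices/arrays so that the
# finite-difference gradient checks in the test suite apply uniformly.

.sigmoid <- function(z) 1 / (1 + exp(-z))

.bceLoss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Glorot-uniform init; all randomness flows from the caller's RNG state
.glorot <- function(nin, nout, dims = c(nin, nout)) {
  s <- sqrt(6 / (nin + nout))
  array(stats::runif(prod(dims), -s, s), dims)
}

# Embedding lookup: X [B, L] integer indices (0 = pad) -> array [B, L, d].
# Pad positions embed to the zero vector, the natural null for masking.
.embed <- function(E, X) {
  B <- nrow(X); L <- ncol(X); d <- ncol(E)
  flat <- as.vector(X)
  Ef <- matrix(0, B * L, d)
  nz <- flat > 0L
  if (any(nz)) Ef[nz, ] <- E[flat[nz], , drop = FALSE]
  array(Ef, c(B, L, d))
}

# Gradient of the embedding matrix from dXe [B, L, d]
.embedGrad <- function(E, X, dXe) {
  B <- nrow(X); L <- ncol(X); d <- ncol(E)
  flat <- as.vector(X)
  dEf <- matrix(dXe, B * L, d)
  dE <- matrix(0, nrow(E), d)
  nz <- flat > 0L
  if (any(nz)) {
    agg <- rowsum(dEf[nz, , drop = FALSE], flat[nz])
    dE[as.integer(rownames(agg)), ] <- agg
  }
  dE
}

# Inverted dropout on a pooled representation; returns list(h, mask)
.dropout <- function(h, rate, train) {
  if (!train || rate <= 0) return(list(h = h, mask = NULL))
  mask <- matrix(stats::rbinom(length(h), 1L, 1 - rate) / (1 - rate),
                 nrow(h), ncol(h))
  list(h = h * mask, mask = mask)
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

.adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dispatch: forward pass of any sub-model kind.
# Returns list(p = probabilities, z = logits, cache = for backward).
.modelForward <- function(kind, params, X, cfg, train = FALSE) {
  switch(kind,
    cnn = .cnnForward(params, X, cfg, train),
    lstm = .lstmForward(params, X, cfg, train),
    attention = .attnForward(params, X, cfg, train),
    transformer = .trfForward(params, X, cfg, train),
    stop("unknown model kind: ", kind))
}

# Dispatch: backward pass; dz = dLoss/dlogit (length B).
.modelBackward <- function(kind, params, cache, dz) {
  switch(kind,
    cnn = .cnnBackward(params, cache, dz),
    lstm = .lstmBackward(params, cache, dz),
    attention = .attnBackward(params, cache, dz),
    transformer = .trfBackward(params, cache, dz))
}

# Dense sigmoid head shared by all models: h [B, H] -> prob [B]
.headForward <- function(h, w, b) {
  z <- as.vector(h %*% w) + as.numeric(b)
  list(z = z, p = .sigmoid(z))
}

.headBackward <- function(h, w, dz) {
  list(dw = t(h) %*% dz, db = sum(dz), dh = dz %*% t(w))
}
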