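# Transformer-encoder classifier: embedding + sinusoidal positional
# encoding, two pre-norm-free (post-norm) encoder blocks of multi-head
# self-attention (pad keys masked) with residual + layer norm and a
# ReLU feed-forward sublayer, masked mean pooling, sigmoid head.
# Integrates global pairwise context across the peptide.

.trfInit <- function(cfg) {
  d <- cfg$embeddingDim; dff <- cfg$ffnDim
  p <- list(E = .glorot(20, d, c(20, d)),
            w = .glorot(d, 1, c(d, 1)), b = 0)
  for (l in seq_len(cfg$blocks)) {
    p[[paste0("Wq", l)]] <- .glorot(d, d)
    p[[paste0("Wk", l)]] <- .glorot(d, d)
    p[[paste0("Wv", l)]] <- .glorot(d, d)
    p[[paste0("Wo", l)]] <- .glorot(d, d)
    p[[paste0("bq", l)]] <- numeric(d)
    p[[paste0("bk", l)]] <- numeric(d)
    p[[paste0("bv", l)]] <- numeric(d)
    p[[paste0("bo", l)]] <- numeric(d)
    p[[paste0("g1", l)]] <- rep(1, d)
    p[[paste0("be1", l)]] <- numeric(d)
    p[[paste0("Wf1", l)]] <- .glorot(d, dff)
    p[[paste0("bf1", l)]] <- numeric(dff)
    p[[paste0("Wf2", l)]] <- .glorot(dff, d)
    p[[paste0("bf2", l)]] <- numeric(d)
    p[[paste0("g2", l)]] <- rep(1, d)
    p[[paste0("be2", l)]] <- numeric(d)
  }
  p
}

.posEncoding <- function(L, d) {
  P <- matrix(0, L, d)
  pos <- seq_len(L) - 1L
  for (i in seq_len(d %/% 2)) {
    f <- 1 / 10000^(2 * (i - 1) / d)
    P[, 2 * i - 1] <- sin(pos * f)
    P[, 2 * i] <- cos(pos * f)
  }
  P
}

# layer norm over the feature dimension of a flat [N, d] matrix
.lnForward <- function(x, g, be, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(va + eps)
  xhat <- xc * invstd
  list(y = xhat * rep(g, each = nrow(x)) +
         rep(be, each = nrow(x)),
       xhat = xhat, invstd = invstd)
}

.lnBackward <- function(dy, ln, g) {
  xhat <- ln$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- ln$invstd * (dxhat - rowMeans(dxhat) -
                       xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dgamma, dbe = dbeta)
}

.trfForward <- function(params, X, cfg, train = FALSE) {
  B <- nrow(X); L <- ncol(X); d <- cfg$embeddingDim
  nh <- cfg$heads; dh <- d %/% nh
  M <- (X > 0L) * 1
  Xe <- .embed(params$E, X)
  P <- .posEncoding(L, d)
  H <- Xe
  for (t in seq_len(L))
    H[, t, ] <- H[, t, ] + rep(P[t, ], each = B)
  blocks <- vector("list", cfg$blocks)
  for (l in seq_len(cfg$blocks)) {
    Hf <- matrix(H, B * L, d)
    Q <- Hf %*% params[[paste0("Wq", l)]] +
      rep(params[[paste0("bq", l)]], each = B * L)
    K <- Hf %*% params[[paste0("Wk", l)]] +
      rep(params[[paste0("bk", l)]], each = B * L)
    V <- Hf %*% params[[paste0("Wv", l)]] +
      rep(params[[paste0("bv", l)]], each = B * L)
    Qa <- array(Q, c(B, L, d)); Ka <- array(K, c(B, L, d))
    Va <- array(V, c(B, L, d))
    A <- vector("list", B)          # per-sample attention per head
    Ca <- array(0, c(B, L, d))
    sc <- 1 / sqrt(dh)
    for (bb in seq_len(B)) {
      Ab <- vector("list", nh)
      keyMask <- M[bb, ] == 0
      for (hh in seq_len(nh)) {
        cols <- ((hh - 1) * dh + 1):(hh * dh)
        S <- (Qa[bb, , cols] %*% t(Ka[bb, , cols])) * sc
        if (any(keyMask)) S[, keyMask] <- -1e30
        S <- S - apply(S, 1L, max)
        Ex <- exp(S)
        At <- Ex / rowSums(Ex)
        Ab[[hh]] <- At
        Ca[bb, , cols] <- At %*% Va[bb, , cols]
      }
      A[[bb]] <- Ab
    }
    Cf <- matrix(Ca, B * L, d)
    Of <- Cf %*% params[[paste0("Wo", l)]] +
      rep(params[[paste0("bo", l)]], each = B * L)
    R1 <- Hf + Of
    ln1 <- .lnForward(R1, params[[paste0("g1", l)]],
                      params[[paste0("be1", l)]])
    F1pre <- ln1$y %*% params[[paste0("Wf1", l)]] +
      rep(params[[paste0("bf1", l)]], each = B * L)
    F1 <- pmax(F1pre, 0)
    F2 <- F1 %*% params[[paste0("Wf2", l)]] +
      rep(params[[paste0("bf2", l)]], each = B * L)
    R2 <- ln1$y + F2
    ln2 <- .lnForward(R2, params[[paste0("g2", l)]],
                      params[[paste0("be2", l)]])
    blocks[[l]] <- list(Hf = Hf, Qa = Qa, Ka = Ka, Va = Va, A = A,
                        Ca = Ca, ln1 = ln1, F1pre = F1pre, F1 = F1,
                        ln1y = ln1$y, ln2 = ln2)
    H <- array(ln2$y, c(B, L, d))
  }
  denom <- pmax(rowSums(M), 1)   # all-masked input pools to zero
  pooled <- matrix(0, B, d)
  for (t in seq_len(L))
    pooled <- pooled + M[, t] * matrix(H[, t, ], B, d)
  pooled <- pooled / denom
  dr <- .dropout(pooled, cfg$dropout, train)
  hd <- .headForward(dr$h, params$w, params$b)
  list(p = hd$p, z = hd$z,
       cache = list(X = X, M = M, blocks = blocks, Hout = H,
                    denom = denom, hdrop = dr$h, mask = dr$mask,
                    cfg = cfg))
}

.trfBackward <- function(params, cache, dz) {
  cfg <- cache$cfg
  B <- nrow(cache$X); L <- ncol(cache$X); d <- cfg$embeddingDim
  nh <- cfg$heads; dh <- d %/% nh
  M <- cache$M
  hb <- .headBackward(cache$hdrop, params$w, dz)
  dpooled <- hb$dh
  if (!is.null(cache$mask)) dpooled <- dpooled * cache$mask
  dpooled <- dpooled / cache$denom
  dH <- array(0, c(B, L, d))
  for (t in seq_len(L))
    dH[, t, ] <- M[, t] * dpooled
  grads <- list(w = hb$dw, b = hb$db)
  sc <- 1 / sqrt(dh)
  for (l in rev(seq_len(cfg$blocks))) {
    bl <- cache$blocks[[l]]
    dy2 <- matrix(dH, B * L, d)
    l2 <- .lnBackward(dy2, bl$ln2, params[[paste0("g2", l)]])
    grads[[paste0("g2", l)]] <- l2$dg
    grads[[paste0("be2", l)]] <- l2$dbe
    dR2 <- l2$dx
    # R2 = ln1y + F2(ln1y)
    dF2 <- dR2
    grads[[paste0("Wf2", l)]] <- t(bl$F1) %*% dF2
    grads[[paste0("bf2", l)]] <- colSums(dF2)
    dF1 <- (dF2 %*% t(params[[paste0("Wf2", l)]])) * (bl$F1pre > 0)
    grads[[paste0("Wf1", l)]] <- t(bl$ln1y) %*% dF1
    grads[[paste0("bf1", l)]] <- colSums(dF1)
    dln1y <- dR2 + dF1 %*% t(params[[paste0("Wf1", l)]])
    l1 <- .lnBackward(dln1y, bl$ln1, params[[paste0("g1", l)]])
    grads[[paste0("g1", l)]] <- l1$dg
    grads[[paste0("be1", l)]] <- l1$dbe
    dR1 <- l1$dx
    # R1 = Hf + Cf Wo + bo
    dOf <- dR1
    Cf <- matrix(bl$Ca, B * L, d)
    grads[[paste0("Wo", l)]] <- t(Cf) %*% dOf
    grads[[paste0("bo", l)]] <- colSums(dOf)
    dCf <- dOf %*% t(params[[paste0("Wo", l)]])
    dCa <- array(dCf, c(B, L, d))
    dQa <- array(0, c(B, L, d)); dKa <- array(0, c(B, L, d))
    dVa <- array(0, c(B, L, d))
    for (bb in seq_len(B)) {
      for (hh in seq_len(nh)) {
        cols <- ((hh - 1) * dh + 1):(hh * dh)
        At <- bl$A[[bb]][[hh]]
        dC <- dCa[bb, , cols]
        Vb <- bl$Va[bb, , cols]
        dA <- dC %*% t(Vb)
        dVa[bb, , cols] <- t(At) %*% dC
        rowS <- rowSums(dA * At)
        dS <- At * (dA - rowS)
        dQa[bb, , cols] <- (dS %*% bl$Ka[bb, , cols]) * sc
        dKa[bb, , cols] <- (t(dS) %*% bl$Qa[bb, , cols]) * sc
      }
    }
    dQ <- matrix(dQa, B * L, d); dK <- matrix(dKa, B * L, d)
    dV <- matrix(dVa, B * L, d)
    grads[[paste0("Wq", l)]] <- t(bl$Hf) %*% dQ
    grads[[paste0("bq", l)]] <- colSums(dQ)
    grads[[paste0("Wk", l)]] <- t(bl$Hf) %*% dK
    grads[[paste0("bk", l)]] <- colSums(dK)
    grads[[paste0("Wv", l)]] <- t(bl$Hf) %*% dV
    grads[[paste0("bv", l)]] <- colSums(dV)
    dHf <- dR1 + dQ %*% t(params[[paste0("Wq", l)]]) +
      dK %*% t(params[[paste0("Wk", l)]]) +
      dV %*% t(params[[paste0("Wv", l)]])
    dH <- array(dHf, c(B, L, d))
  }
  # positional encoding is a constant shift; gradient passes through
  grads$E <- .embedGrad(params$E, cache$X, dH)
  grads
}
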