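# Attention-pooling classifier: embedding plus sinusoidal positional
# encoding, additive (tanh) scoring against several learned query
# vectors (structured self-attention pooling), softmax weights over
# non-pad positions per query, concatenated weighted sums, sigmoid
# head. Learns which residue positions matter and exposes
# interpretable weights.

.attnInit <- function(cfg) {
  d <- cfg$embeddingDim; m <- cfg$attnDim; q <- cfg$attnQueries
  h <- cfg$attnHidden
  list(E = .glorot(20, d, c(20, d)),
       Wa = .glorot(d, m), ba = numeric(m),
       v = .glorot(m, q, c(m, q)),
       Wh = .glorot(q * d, h), bh = numeric(h),
       w = .glorot(h, 1, c(h, 1)), b = 0)
}

.attnForward <- function(params, X, cfg, train = FALSE) {
  Xe <- .embed(params$E, X)
  B <- dim(Xe)[1]; L <- dim(Xe)[2]; d <- dim(Xe)[3]
  Q <- ncol(params$v)
  P <- .posEncoding(L, d)
  Xp <- Xe
  for (t in seq_len(L))
    Xp[, t, ] <- Xp[, t, ] + rep(P[t, ], each = B)
  M <- (X > 0L) * 1
  U <- vector("list", L)
  S <- array(0, c(B, L, Q))
  for (t in seq_len(L)) {
    xt <- matrix(Xp[, t, ], B, d)
    U[[t]] <- tanh(xt %*% params$Wa +
                   matrix(params$ba, B, length(params$ba),
                          byrow = TRUE))
    S[, t, ] <- U[[t]] %*% params$v
  }
  alpha <- array(0, c(B, L, Q))
  pooled <- matrix(0, B, Q * d)
  for (qq in seq_len(Q)) {
    Sq <- matrix(S[, , qq], B, L)
    Sq[M == 0] <- -1e30                   # pads get zero weight
    Sq <- Sq - apply(Sq, 1L, max)
    Ex <- exp(Sq)
    aq <- Ex / rowSums(Ex)
    alpha[, , qq] <- aq
    cols <- ((qq - 1) * d + 1):(qq * d)
    for (t in seq_len(L))
      pooled[, cols] <- pooled[, cols] + aq[, t] * matrix(Xp[, t, ], B, d)
  }
  dr <- .dropout(pooled, cfg$dropout, train)
  Hh <- tanh(dr$h %*% params$Wh +
               matrix(params$bh, B, length(params$bh), byrow = TRUE))
  hd <- .headForward(Hh, params$w, params$b)
  list(p = hd$p, z = hd$z,
       cache = list(X = X, Xp = Xp, M = M, U = U, alpha = alpha,
                    pooled = pooled, hdrop = dr$h, Hh = Hh,
                    mask = dr$mask))
}

.attnBackward <- function(params, cache, dz) {
  hb <- .headBackward(cache$Hh, params$w, dz)
  dHh <- hb$dh * (1 - cache$Hh * cache$Hh)
  dWh <- t(cache$hdrop) %*% dHh
  dbh <- colSums(dHh)
  dpooled <- dHh %*% t(params$Wh)
  if (!is.null(cache$mask)) dpooled <- dpooled * cache$mask
  Xp <- cache$Xp; alpha <- cache$alpha
  B <- dim(Xp)[1]; L <- dim(Xp)[2]; d <- dim(Xp)[3]
  Q <- ncol(params$v)
  dXp <- array(0, dim(Xp))
  dS <- array(0, c(B, L, Q))
  for (qq in seq_len(Q)) {
    cols <- ((qq - 1) * d + 1):(qq * d)
    dpq <- dpooled[, cols, drop = FALSE]
    aq <- matrix(alpha[, , qq], B, L)
    dalpha <- matrix(0, B, L)
    for (t in seq_len(L)) {
      xt <- matrix(Xp[, t, ], B, d)
      dalpha[, t] <- rowSums(dpq * xt)
      dXp[, t, ] <- dXp[, t, ] + aq[, t] * dpq
    }
    rowS <- rowSums(aq * dalpha)
    dS[, , qq] <- aq * (dalpha - rowS)    # zero at pads (alpha = 0)
  }
  dWa <- array(0, dim(params$Wa)); dba <- numeric(length(params$ba))
  dv <- array(0, dim(params$v))
  for (t in seq_len(L)) {
    ut <- cache$U[[t]]
    dSt <- matrix(dS[, t, ], B, Q)
    dv <- dv + t(ut) %*% dSt
    du <- dSt %*% t(params$v)
    da <- du * (1 - ut * ut)
    xt <- matrix(Xp[, t, ], B, d)
    dWa <- dWa + t(xt) %*% da
    dba <- dba + colSums(da)
    dXp[, t, ] <- dXp[, t, ] + da %*% t(params$Wa)
  }
  # positional encoding is constant: dXe == dXp
  list(E = .embedGrad(params$E, cache$X, dXp),
       Wa = dWa, ba = dba, v = dv, Wh = dWh, bh = dbh,
       w = hb$dw, b = hb$db)
}
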