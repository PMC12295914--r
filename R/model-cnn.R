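# 1-D convolutional classifier: embedding, two valid-padding conv
# blocks (kernel 3, ReLU), global max pooling over positions, sigmoid
# head. Captures short local motifs (di-/tri-peptide patterns).

.cnnInit <- function(cfg) {
  d <- cfg$embeddingDim; F1 <- cfg$filters; F2 <- cfg$filters
  list(E = .glorot(20, d, c(20, d)),
       W1 = .glorot(3 * d, F1, c(3, d, F1)), b1 = numeric(F1),
       W2 = .glorot(3 * F1, F2, c(3, F1, F2)), b2 = numeric(F2),
       w = .glorot(F2, 1, c(F2, 1)), b = 0)
}

# valid 1-D convolution of A [B, T, Cin] with W [k, Cin, Cout]
.conv1d <- function(A, W, b) {
  k <- dim(W)[1]; B <- dim(A)[1]; Tin <- dim(A)[2]; Cout <- dim(W)[3]
  Tout <- Tin - k + 1L
  Z <- array(rep(b, each = B * Tout), c(B, Tout, Cout))
  for (t in seq_len(Tout))
    for (kk in seq_len(k))
      Z[, t, ] <- Z[, t, ] + A[, t + kk - 1L, ] %*% W[kk, , ]
  Z
}

.conv1dBackward <- function(A, W, dZ) {
  k <- dim(W)[1]; B <- dim(A)[1]; Tout <- dim(dZ)[2]
  dA <- array(0, dim(A)); dW <- array(0, dim(W))
  for (t in seq_len(Tout)) {
    dzt <- dZ[, t, , drop = TRUE]
    if (is.null(dim(dzt))) dzt <- matrix(dzt, B)
    for (kk in seq_len(k)) {
      dA[, t + kk - 1L, ] <- dA[, t + kk - 1L, ] + dzt %*% t(W[kk, , ])
      dW[kk, , ] <- dW[kk, , ] + t(A[, t + kk - 1L, ]) %*% dzt
    }
  }
  list(dA = dA, dW = dW, db = apply(dZ, 3L, sum))
}

# global max pool over dim 2; returns h [B, C] and argmax [B, C]
.maxPool <- function(A) {
  B <- dim(A)[1]; Tn <- dim(A)[2]; C <- dim(A)[3]
  h <- A[, 1L, , drop = TRUE]
  if (is.null(dim(h))) h <- matrix(h, B)
  arg <- matrix(1L, B, C)
  if (Tn > 1L) for (t in 2:Tn) {
    At <- A[, t, , drop = TRUE]
    if (is.null(dim(At))) At <- matrix(At, B)
    upd <- At > h
    h[upd] <- At[upd]
    arg[upd] <- t
  }
  list(h = h, arg = arg)
}

.cnnForward <- function(params, X, cfg, train = FALSE) {
  Xe <- .embed(params$E, X)
  Z1 <- .conv1d(Xe, params$W1, params$b1)
  A1 <- pmax(Z1, 0)
  Z2 <- .conv1d(A1, params$W2, params$b2)
  A2 <- pmax(Z2, 0)
  mp <- .maxPool(A2)
  dr <- .dropout(mp$h, cfg$dropout, train)
  hd <- .headForward(dr$h, params$w, params$b)
  list(p = hd$p, z = hd$z,
       cache = list(X = X, Xe = Xe, Z1 = Z1, A1 = A1, Z2 = Z2,
                    A2 = A2, arg = mp$arg, hdrop = dr$h,
                    mask = dr$mask))
}

.cnnBackward <- function(params, cache, dz) {
  hb <- .headBackward(cache$hdrop, params$w, dz)
  dh <- hb$dh
  if (!is.null(cache$mask)) dh <- dh * cache$mask
  B <- dim(cache$A2)[1]; T2 <- dim(cache$A2)[2]; C <- dim(cache$A2)[3]
  dA2 <- array(0, dim(cache$A2))
  bIdx <- rep(seq_len(B), C)
  fIdx <- rep(seq_len(C), each = B)
  dA2[cbind(bIdx, as.vector(cache$arg), fIdx)] <- as.vector(dh)
  dZ2 <- dA2 * (cache$Z2 > 0)
  c2 <- .conv1dBackward(cache$A1, params$W2, dZ2)
  dZ1 <- c2$dA * (cache$Z1 > 0)
  c1 <- .conv1dBackward(cache$Xe, params$W1, dZ1)
  list(E = .embedGrad(params$E, cache$X, c1$dA),
       W1 = c1$dW, b1 = c1$db, W2 = c2$dW, b2 = c2$db,
       w = hb$dw, b = hb$db)
}
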