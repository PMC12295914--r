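# Bidirectional LSTM classifier: embedding, one LSTM layer per
# direction with pad masking (state carries unchanged through pads, so
# the final state is the state at the true sequence end), concatenated
# final hidden states, sigmoid head. Captures long-range order.

.lstmInit <- function(cfg) {
  d <- cfg$embeddingDim; H <- cfg$hidden
  p <- list(E = .glorot(20, d, c(20, d)),
            Wxf = .glorot(d, 4 * H), Whf = .glorot(H, 4 * H),
            bf = numeric(4 * H),
            Wxb = .glorot(d, 4 * H), Whb = .glorot(H, 4 * H),
            bb = numeric(4 * H),
            w = .glorot(2 * H, 1, c(2 * H, 1)), b = 0)
  # forget-gate bias 1: standard trick for stable early training
  p$bf[(H + 1):(2 * H)] <- 1
  p$bb[(H + 1):(2 * H)] <- 1
  p
}

# one direction; tsteps is the time order (1:L forward, L:1 backward)
.lstmRun <- function(Xe, M, Wx, Wh, b, tsteps) {
  B <- dim(Xe)[1]; H <- nrow(Wh)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  steps <- vector("list", length(tsteps))
  for (s in seq_along(tsteps)) {
    t <- tsteps[s]
    x <- Xe[, t, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, B)
    a <- x %*% Wx + h %*% Wh + matrix(b, B, 4 * H, byrow = TRUE)
    i <- .sigmoid(a[, 1:H, drop = FALSE])
    f <- .sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
    cNew <- f * cc + i * g
    hNew <- o * tanh(cNew)
    m <- M[, t]
    hOut <- m * hNew + (1 - m) * h
    cOut <- m * cNew + (1 - m) * cc
    steps[[s]] <- list(t = t, x = x, hPrev = h, cPrev = cc, i = i,
                       f = f, g = g, o = o, cNew = cNew, m = m)
    h <- hOut; cc <- cOut
  }
  list(h = h, steps = steps)
}

.lstmRunBackward <- function(run, Wx, Wh, dhFinal, dXe, M) {
  H <- ncol(dhFinal)
  B <- nrow(dhFinal)
  dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh))
  db <- numeric(4 * H)
  dh <- dhFinal; dc <- matrix(0, B, H)
  for (s in rev(seq_along(run$steps))) {
    st <- run$steps[[s]]
    m <- st$m
    tc <- tanh(st$cNew)
    dhNew <- dh * m
    dhCarry <- dh * (1 - m)
    dcNew <- dc * m + dhNew * st$o * (1 - tc * tc)
    dcCarry <- dc * (1 - m)
    dao <- (dhNew * tc) * st$o * (1 - st$o)
    dai <- (dcNew * st$g) * st$i * (1 - st$i)
    daf <- (dcNew * st$cPrev) * st$f * (1 - st$f)
    dag <- (dcNew * st$i) * (1 - st$g * st$g)
    dA <- cbind(dai, daf, dag, dao)
    dWx <- dWx + t(st$x) %*% dA
    dWh <- dWh + t(st$hPrev) %*% dA
    db <- db + colSums(dA)
    dXe[, st$t, ] <- dXe[, st$t, ] + dA %*% t(Wx)
    dh <- dhCarry + dA %*% t(Wh)
    dc <- dcCarry + dcNew * st$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dXe = dXe)
}

.lstmForward <- function(params, X, cfg, train = FALSE) {
  Xe <- .embed(params$E, X)
  M <- (X > 0L) * 1
  L <- ncol(X)
  fwd <- .lstmRun(Xe, M, params$Wxf, params$Whf, params$bf, 1:L)
  bwd <- .lstmRun(Xe, M, params$Wxb, params$Whb, params$bb, L:1)
  h <- cbind(fwd$h, bwd$h)
  dr <- .dropout(h, cfg$dropout, train)
  hd <- .headForward(dr$h, params$w, params$b)
  list(p = hd$p, z = hd$z,
       cache = list(X = X, Xe = Xe, M = M, fwd = fwd, bwd = bwd,
                    hdrop = dr$h, mask = dr$mask))
}

.lstmBackward <- function(params, cache, dz) {
  hb <- .headBackward(cache$hdrop, params$w, dz)
  dh <- hb$dh
  if (!is.null(cache$mask)) dh <- dh * cache$mask
  H <- ncol(dh) / 2L
  dXe <- array(0, dim(cache$Xe))
  gf <- .lstmRunBackward(cache$fwd, params$Wxf, params$Whf,
                         dh[, 1:H, drop = FALSE], dXe, cache$M)
  gb <- .lstmRunBackward(cache$bwd, params$Wxb, params$Whb,
                         dh[, (H + 1):(2 * H), drop = FALSE],
                         gf$dXe, cache$M)
  list(E = .embedGrad(params$E, cache$X, gb$dXe),
       Wxf = gf$dWx, Whf = gf$dWh, bf = gf$db,
       Wxb = gb$dWx, Whb = gb$dWh, bb = gb$db,
       w = hb$dw, b = hb$db)
}
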