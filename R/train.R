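#' Hyperparameter configuration for one sub-model
#'
#' Defaults are sized for corpora of a few hundred peptides on one CPU:
#' embedding 32, CNN 64 filters (kernel 3, two blocks), BiLSTM hidden
#' 64, attention dim 32, transformer 2 blocks x 4 heads (model dim 32,
#' FFN 64), dropout 0.1 on the pooled representation, Adam lr 1e-3,
#' minibatch 64, at most 200 epochs with early stopping on a seeded
#' validation fold.
#'
#' @param kind \code{"cnn"}, \code{"lstm"}, \code{"attention"} or
#'   \code{"transformer"}.
#' @param embeddingDim residue embedding dimension.
#' @param filters CNN filters per conv block.
#' @param hidden LSTM hidden units per direction.
#' @param attnDim attention scoring dimension.
#' @param attnQueries number of learned attention queries whose pooled
#'   vectors are concatenated (structured self-attention pooling).
#' @param attnHidden hidden units of the attention model's tanh head.
#' @param heads,blocks,ffnDim transformer geometry; \code{embeddingDim}
#'   must be divisible by \code{heads}.
#' @param dropout dropout rate on the pooled representation.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batchSize minibatch size.
#' @param valFraction fraction of the training data held out (per
#'   class) as the early-stopping validation fold.
#' @param patience epochs without validation improvement before
#'   stopping.
#' @param seed integer seed governing all randomness (init, shuffling,
#'   dropout, validation fold).
#' @return A named list with class \code{submodel_config}.
#' @export
subModelConfig <- function(kind = c("cnn", "lstm", "attention",
                                    "transformer"),
                           embeddingDim = 32L, filters = 64L,
                           hidden = 64L, attnDim = 32L,
                           attnQueries = 4L, attnHidden = 16L,
                           heads = 4L,
                           blocks = 2L, ffnDim = 64L, dropout = 0.1,
                           lr = 1e-3, epochs = 200L, batchSize = 64L,
                           valFraction = 0.15, patience = 25L,
                           seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(embeddingDim > 0, filters > 0, hidden > 0, attnDim > 0,
            attnQueries > 0, attnHidden > 0,
            heads > 0, blocks > 0, ffnDim > 0, dropout >= 0,
            dropout < 1, lr > 0, epochs > 0, batchSize > 0,
            valFraction > 0, valFraction < 0.5)
  if (kind == "transformer" && embeddingDim %% heads != 0L)
    stop("embeddingDim must be divisible by heads")
  structure(list(kind = kind, embeddingDim = as.integer(embeddingDim),
                 filters = as.integer(filters),
                 hidden = as.integer(hidden),
                 attnDim = as.integer(attnDim),
                 attnQueries = as.integer(attnQueries),
                 attnHidden = as.integer(attnHidden),
                 heads = as.integer(heads), blocks = as.integer(blocks),
                 ffnDim = as.integer(ffnDim), dropout = dropout,
                 lr = lr, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 valFraction = valFraction,
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "submodel_config")
}

.modelInit <- function(cfg) {
  switch(cfg$kind,
    cnn = .cnnInit(cfg), lstm = .lstmInit(cfg),
    attention = .attnInit(cfg), transformer = .trfInit(cfg))
}

#' Train one sub-model of the umami ensemble
#'
#' Trains a single sequence classifier by minibatch Adam on binary
#' cross-entropy, holding out a seeded stratified validation fold for
#' early stopping; the parameters achieving the best validation loss
#' are kept. For a fixed seed, corpus and configuration the result is
#' reproducible on one machine.
#'
#' @param sequences character vector of training peptides.
#' @param labels binary 0/1 labels (1 = umami).
#' @param config a [subModelConfig()].
#' @param encoding an [encodingSpec()]; all peptides must fit
#'   \code{maxLen}.
#' @param quiet suppress the per-training message.
#' @return A [UmamiSubModel-class].
#' @examples
#' corpus <- syntheticCorpus(30, seed = 3)
#' m <- trainSubModel(corpus$sequence, corpus$label,
#'                    subModelConfig("cnn", epochs = 3), encodingSpec(12))
#' predict(m, corpus$sequence[1:2])
#' @export
trainSubModel <- function(sequences, labels,
                          config = subModelConfig("cnn"),
                          encoding = encodingSpec(), quiet = FALSE) {
  stopifnot(inherits(config, "submodel_config"),
            length(sequences) == length(labels),
            length(sequences) > 0L)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  X <- encodePeptides(sequences, encoding)
  restore <- .localSeed(config$seed)
  on.exit(restore())
  constant <- length(unique(labels)) == 1L
  if (constant && !quiet)
    message("constant-label corpus: trained model will degenerate ",
            "to predicting label ", labels[1])
  ## seeded stratified validation fold for early stopping
  n <- length(labels)
  valIdx <- integer()
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    k <- max(1L, round(config$valFraction * length(idx)))
    if (k < length(idx)) valIdx <- c(valIdx, sample(idx, k))
  }
  trIdx <- setdiff(seq_len(n), valIdx)
  if (!length(valIdx)) { valIdx <- trIdx }   # tiny corpora: train=val
  Xtr <- X[trIdx, , drop = FALSE]; ytr <- labels[trIdx]
  Xva <- X[valIdx, , drop = FALSE]; yva <- labels[valIdx]
  params <- .modelInit(config)
  adam <- .adamInit(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- vector("list", config$epochs)
  nb <- nrow(Xtr)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(nb)
    starts <- seq(1L, nb, by = config$batchSize)
    eplosses <- numeric(length(starts))
    for (si in seq_along(starts)) {
      rows <- ord[starts[si]:min(starts[si] + config$batchSize - 1L, nb)]
      Xb <- Xtr[rows, , drop = FALSE]; yb <- ytr[rows]
      fw <- .modelForward(config$kind, params, Xb, config, train = TRUE)
      if (!all(is.finite(fw$z))) stop("non-finite loss during training")
      eplosses[si] <- .bceLoss(fw$p, yb)
      dz <- (fw$p - yb) / length(yb)
      grads <- .modelBackward(config$kind, params, fw$cache, dz)
      upd <- .adamStep(params, grads, adam, lr = config$lr)
      params <- upd$params; adam <- upd$state
    }
    vp <- .modelForward(config$kind, params, Xva, config)$p
    vloss <- .bceLoss(vp, yva)
    hist[[ep]] <- data.frame(epoch = ep,
                             train_loss = mean(eplosses),
                             val_loss = vloss)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = params, epoch = ep)
    } else if (ep - best$epoch >= config$patience) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  if (!quiet)
    message(sprintf("%s: stopped after %d epochs, best val loss %.4f (epoch %d)",
                    config$kind, nrow(history), best$loss, best$epoch))
  new("UmamiSubModel", kind = config$kind, config = unclass(config),
      params = best$params, encoding = encoding, history = history)
}

#' Save or load a trained sub-model artifact
#'
#' The artifact is self-describing: it carries the parameters together
#' with the full configuration (including the training seed) and the
#' encoding specification.
#'
#' @param model an [UmamiSubModel-class].
#' @param path file path (RDS).
#' @return \code{saveSubModel}: invisibly, \code{path};
#'   \code{loadSubModel}: the [UmamiSubModel-class].
#' @export
saveSubModel <- function(model, path) {
  stopifnot(is(model, "UmamiSubModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveSubModel
#' @export
loadSubModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "UmamiSubModel"))
    stop("file does not contain an UmamiSubModel artifact")
  validObject(model)
  model
}

# batched deterministic inference on an encoded matrix
.predictMatrix <- function(model, X, chunk = 2048L) {
  cfg <- model@config
  out <- numeric(nrow(X))
  starts <- seq(1L, nrow(X), by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1L, nrow(X))
    out[rows] <- .modelForward(model@kind, model@params,
                               X[rows, , drop = FALSE], cfg)$p
  }
  out
}

#' Predict umami probabilities with a trained sub-model
#'
#' @param object a [UmamiSubModel-class].
#' @param newdata character vector of peptides, or an integer matrix
#'   already encoded with the model's [encodingSpec()].
#' @param ... unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
setMethod("predict", "UmamiSubModel", function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else
    encodePeptides(newdata, object@encoding)
  .predictMatrix(object, X)
})
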