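#' Assemble a unanimity ensemble from four trained sub-models
#'
#' @param models list of four [UmamiSubModel-class] objects, exactly
#'   one per kind (cnn, lstm, attention, transformer), in any order.
#' @param threshold per-sub-model decision threshold (default 0.5).
#' @return An [UmamiEnsemble-class].
#' @export
umamiEnsemble <- function(models, threshold = 0.5) {
  if (length(models) != 4L ||
      !all(vapply(models, is, logical(1), "UmamiSubModel")))
    stop("ensemble needs exactly four UmamiSubModel objects")
  kinds <- vapply(models, function(m) m@kind, character(1))
  if (!setequal(kinds, c("cnn", "lstm", "attention", "transformer")))
    stop("ensemble needs one model per kind ",
         "(cnn, lstm, attention, transformer)")
  names(models) <- kinds
  new("UmamiEnsemble",
      models = models[c("cnn", "lstm", "attention", "transformer")],
      threshold = threshold)
}

#' Train the four sub-models and combine them
#'
#' Each sub-model gets its own seed derived deterministically from
#' \code{seed} so the four trainings are independent but jointly
#' reproducible.
#'
#' @param sequences,labels the training corpus.
#' @param encoding shared [encodingSpec()].
#' @param seed master integer seed.
#' @param epochs maximum epochs per sub-model.
#' @param threshold unanimity decision threshold.
#' @param quiet suppress per-model training messages.
#' @param ... further arguments passed to [subModelConfig()] for every
#'   kind.
#' @return An [UmamiEnsemble-class].
#' @export
trainEnsemble <- function(sequences, labels, encoding = encodingSpec(),
                          seed = 1L, epochs = 200L, threshold = 0.5,
                          quiet = FALSE, ...) {
  kinds <- c("cnn", "lstm", "attention", "transformer")
  models <- lapply(seq_along(kinds), function(i) {
    cfg <- subModelConfig(kinds[i], epochs = epochs,
                          seed = as.integer(seed) * 101L + i, ...)
    trainSubModel(sequences, labels, cfg, encoding, quiet = quiet)
  })
  umamiEnsemble(models, threshold)
}

#' Ensemble prediction with unanimity vote
#'
#' Runs all four sub-models on each peptide. The ensemble probability
#' is the arithmetic mean of the four probabilities; the unanimity
#' label is TRUE only when every sub-model probability reaches the
#' threshold. The vote is stricter than mean-thresholding: a single
#' dissenting sub-model vetoes a peptide whose mean is high.
#'
#' @param ensemble an [UmamiEnsemble-class].
#' @param peptides character vector of peptides.
#' @return data.frame with columns \code{sequence}, \code{p_cnn},
#'   \code{p_lstm}, \code{p_attention}, \code{p_transformer},
#'   \code{average_prob}, \code{unanimous}.
#' @examples
#' ## the veto rule on hand-made probabilities:
#' ## mean(c(.99, .99, .99, .40)) = 0.8425 but the vote is negative
#' @export
ensemblePredict <- function(ensemble, peptides) {
  stopifnot(is(ensemble, "UmamiEnsemble"), length(peptides) > 0L)
  probs <- vapply(ensemble@models, function(m) predict(m, peptides),
                  numeric(length(peptides)))
  if (is.null(dim(probs)))
    probs <- matrix(probs, 1L,
                    dimnames = list(NULL, names(ensemble@models)))
  out <- data.frame(sequence = peptides,
                    p_cnn = probs[, "cnn"],
                    p_lstm = probs[, "lstm"],
                    p_attention = probs[, "attention"],
                    p_transformer = probs[, "transformer"],
                    stringsAsFactors = FALSE)
  out$average_prob <- rowMeans(probs)
  out$unanimous <- apply(probs >= ensemble@threshold, 1L, all)
  rownames(out) <- NULL
  out
}

#' Combine four per-model probabilities under the unanimity rule
#'
#' The arithmetic core of [ensemblePredict()], exposed for working
#' directly with probability tables: average probability and unanimity
#' flag for one peptide's four sub-model outputs.
#'
#' @param probs numeric vector of exactly four probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return list with \code{average_prob} and \code{unanimous}.
#' @examples
#' combineVotes(c(0.99, 0.998, 0.978, 0.972))  # mean 0.9845, TRUE
#' @export
combineVotes <- function(probs, threshold = 0.5) {
  if (length(probs) != 4L) stop("exactly four sub-model probabilities required")
  stopifnot(all(probs >= 0 & probs <= 1))
  list(average_prob = mean(probs),
       unanimous = all(probs >= threshold))
}

#' Mean-of-models prediction function for attribution
#'
#' Returns a deterministic function mapping an encoded matrix to the
#' ensemble-mean probability, suitable as the model argument of
#' [shapleyPositions()].
#'
#' @param ensemble an [UmamiEnsemble-class].
#' @return function(matrix) -> numeric vector.
#' @export
ensembleMeanFunction <- function(ensemble) {
  models <- ensemble@models
  function(X) {
    probs <- vapply(models, function(m) .predictMatrix(m, X),
                    numeric(nrow(X)))
    if (is.null(dim(probs))) probs <- matrix(probs, 1L)
    rowMeans(probs)
  }
}
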