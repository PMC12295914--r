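# Position-wise Shapley attribution. Players are peptide positions;
# an "absent" position is replaced by the pad index 0, the encoding's
# natural null (the models embed it as the zero vector). Exact mode
# enumerates all 2^L coalitions; sampled mode uses antithetic
# permutation sampling.

# resolve a model argument to (fn: encoded matrix -> probs, encoding)
.attrFunction <- function(model, encoding = NULL) {
  if (is(model, "UmamiSubModel"))
    return(list(fn = function(X) .predictMatrix(model, X),
                encoding = model@encoding))
  if (is(model, "UmamiEnsemble"))
    return(list(fn = ensembleMeanFunction(model),
                encoding = model@models[[1]]@encoding))
  if (is.function(model)) {
    if (is.null(encoding)) encoding <- encodingSpec()
    return(list(fn = model, encoding = encoding))
  }
  stop("model must be an UmamiSubModel, UmamiEnsemble or a function")
}

#' Shapley values of peptide positions for a model prediction
#'
#' Attributes a model's output probability to the individual positions
#' of one peptide. Position \code{i} is a player; a coalition is a set
#' of present positions, absent positions being masked to the pad
#' index. In \code{"exact"} mode all \code{2^L} coalitions are
#' evaluated and the efficiency axiom holds to numerical precision
#' (\code{baseValue + sum(values) == prediction}); in \code{"sampled"}
#' mode values are Monte-Carlo averages of marginal contributions over
#' random permutations (each used forwards and reversed, which makes
#' the estimate exactly efficient as well).
#'
#' @param model an [UmamiSubModel-class], an [UmamiEnsemble-class]
#'   (explained through its mean probability), or a function mapping
#'   an encoded integer matrix to probabilities.
#' @param peptide a single peptide string, length at most
#'   \code{maxLen}; exact mode requires length <= 15.
#' @param mode \code{"exact"} or \code{"sampled"}.
#' @param nSamples number of permutations in sampled mode (>= 10).
#' @param seed RNG seed for sampled mode.
#' @param encoding [encodingSpec()] when \code{model} is a bare
#'   function.
#' @return A [PositionAttribution-class] with values named
#'   \code{Pos_0..Pos_{L-1}}.
#' @examples
#' f <- function(X) as.numeric(X[, 1] == 3)  # fires iff Pos_0 == 'D'
#' shapleyPositions(f, "DAA", mode = "exact", encoding = encodingSpec(5))
#' @export
shapleyPositions <- function(model, peptide,
                             mode = c("exact", "sampled"),
                             nSamples = 200L, seed = 1L,
                             encoding = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(peptide) == 1L, nchar(peptide) >= 1L)
  mf <- .attrFunction(model, encoding)
  L <- nchar(peptide)
  if (L > mf$encoding@maxLen)
    stop("peptide longer than the encoding maxLen")
  x <- as.vector(encodePeptides(peptide, mf$encoding))
  if (mode == "exact") {
    if (L > 15L)
      stop("exact mode enumerates 2^L coalitions; L <= 15 required")
    nS <- 2^L
    present <- matrix(FALSE, nS, L)
    s <- 0:(nS - 1L)
    for (i in seq_len(L))
      present[, i] <- bitwAnd(s, bitwShiftL(1L, i - 1L)) > 0L
    X <- matrix(0L, nS, mf$encoding@maxLen)
    for (i in seq_len(L)) X[present[, i], i] <- x[i]
    f <- mf$fn(X)
    size <- rowSums(present)
    # weight |S|! (L-1-|S|)! / L! via log-factorials
    wt <- exp(lfactorial(size) + lfactorial(L - 1L - pmin(size, L - 1L)) -
                lfactorial(L))
    vals <- numeric(L)
    for (i in seq_len(L)) {
      s0 <- which(!present[, i])
      s1 <- s0 + 2^(i - 1L)
      vals[i] <- sum(wt[s0] * (f[s1] - f[s0]))
    }
    base <- f[1L]; pred <- f[nS]
    nSamples <- 0L; seedUsed <- NA_integer_
  } else {
    nSamples <- as.integer(nSamples)
    if (nSamples < 10L) stop("sampled mode requires nSamples >= 10")
    restore <- .localSeed(seed)
    on.exit(restore())
    perms <- vector("list", 2L * nSamples)
    for (k in seq_len(nSamples)) {
      p <- sample(L)
      perms[[2L * k - 1L]] <- p
      perms[[2L * k]] <- rev(p)      # antithetic pair
    }
    # batch every prefix coalition of every permutation
    rowsPer <- L + 1L
    X <- matrix(0L, length(perms) * rowsPer, mf$encoding@maxLen)
    for (k in seq_along(perms)) {
      p <- perms[[k]]
      off <- (k - 1L) * rowsPer
      for (j in seq_len(L)) {
        rows <- off + (j + 1L):rowsPer
        X[rows, p[j]] <- x[p[j]]     # position enters at prefix j
      }
    }
    f <- mf$fn(X)
    vals <- numeric(L)
    for (k in seq_along(perms)) {
      p <- perms[[k]]
      off <- (k - 1L) * rowsPer
      contrib <- diff(f[off + seq_len(rowsPer)])
      vals[p] <- vals[p] + contrib
    }
    vals <- vals / length(perms)
    base <- f[1L]
    pred <- f[rowsPer]
    seedUsed <- as.integer(seed)
  }
  names(vals) <- paste0("Pos_", seq_len(L) - 1L)
  new("PositionAttribution", sequence = peptide, values = vals,
      baseValue = base, prediction = pred, mode = mode,
      nSamples = nSamples, seed = seedUsed)
}

#' Waterfall view of a position attribution
#'
#' Orders contributions by absolute value (largest first) and
#' accumulates them from the base value; in exact mode the last
#' cumulative value equals the prediction.
#'
#' @param attr a [PositionAttribution-class].
#' @return data.frame with columns \code{feature}, \code{value},
#'   \code{cumulative}.
#' @export
waterfallData <- function(attr) {
  stopifnot(is(attr, "PositionAttribution"))
  ord <- order(-abs(attr@values))
  v <- attr@values[ord]
  data.frame(feature = names(v), value = unname(v),
             cumulative = attr@baseValue + cumsum(unname(v)),
             stringsAsFactors = FALSE)
}

#' Global position importance over a peptide set
#'
#' Mean absolute Shapley value per position across a dataset — the
#' "which positions drive umami prediction" view. Positions are
#' averaged over the peptides long enough to have them.
#'
#' @param model as in [shapleyPositions()].
#' @param peptides character vector of peptides.
#' @param mode,nSamples,seed,encoding passed to [shapleyPositions()]
#'   (in sampled mode peptide \code{i} uses seed \code{seed + i} so
#'   draws are independent but reproducible).
#' @return data.frame with columns \code{feature}, \code{position}
#'   (0-based), \code{importance}, sorted by importance descending.
#' @export
globalImportance <- function(model, peptides, mode = c("exact", "sampled"),
                             nSamples = 200L, seed = 1L,
                             encoding = NULL) {
  mode <- match.arg(mode)
  if (!length(peptides)) stop("empty dataset")
  Lmax <- max(nchar(peptides))
  tot <- numeric(Lmax); cnt <- integer(Lmax)
  for (i in seq_along(peptides)) {
    at <- shapleyPositions(model, peptides[[i]], mode = mode,
                           nSamples = nSamples, seed = seed + i,
                           encoding = encoding)
    L <- length(at@values)
    tot[seq_len(L)] <- tot[seq_len(L)] + abs(at@values)
    cnt[seq_len(L)] <- cnt[seq_len(L)] + 1L
  }
  imp <- tot / cnt
  out <- data.frame(feature = paste0("Pos_", seq_len(Lmax) - 1L),
                    position = seq_len(Lmax) - 1L,
                    importance = imp, stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
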