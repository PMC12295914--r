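#' Confusion-matrix tally for binary predictions
#'
#' @param labels,predictions equal-length binary 0/1 vectors (1 =
#'   positive/umami).
#' @return Named list with integer counts \code{TP}, \code{FP},
#'   \code{TN}, \code{FN}.
#' @export
confusionCounts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (!all(labels %in% c(0L, 1L)) || !all(predictions %in% c(0L, 1L)))
    stop("labels and predictions must be binary 0/1")
  list(TP = sum(labels == 1L & predictions == 1L),
       FP = sum(labels == 0L & predictions == 1L),
       TN = sum(labels == 0L & predictions == 0L),
       FN = sum(labels == 1L & predictions == 0L))
}

#' Precision, recall, specificity, accuracy and F1
#'
#' The five standard closed forms: Pr = TP/(TP+FP), Rc = TP/(TP+FN),
#' Sp = TN/(TN+FP), ACC = (TP+TN)/total, F1 = 2 Pr Rc/(Pr+Rc). A
#' zero-denominator ratio is reported as \code{NaN} with a warning,
#' never silently as 0.
#'
#' @param counts result of [confusionCounts()] or a list with TP, FP,
#'   TN, FN.
#' @return Named numeric vector \code{c(Pr, Rc, Sp, ACC, F1)}.
#' @examples
#' computeMetrics(list(TP = 3, FP = 1, TN = 5, FN = 1))
#' @export
computeMetrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  stopifnot(all(c(TP, FP, TN, FN) >= 0))
  total <- TP + FP + TN + FN
  if (total == 0) stop("all confusion counts are zero")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NaN")
      return(NaN)
    }
    num / den
  }
  Pr <- ratio(TP, TP + FP, "precision")
  Rc <- ratio(TP, TP + FN, "recall")
  Sp <- ratio(TN, TN + FP, "specificity")
  ACC <- (TP + TN) / total
  F1 <- f1Score(Pr, Rc)
  c(Pr = Pr, Rc = Rc, Sp = Sp, ACC = ACC, F1 = F1)
}

#' @rdname computeMetrics
#' @param Pr,Rc precision and recall as fractions.
#' @return \code{f1Score}: the harmonic mean 2 Pr Rc/(Pr+Rc), NaN when
#'   Pr + Rc = 0.
#' @export
f1Score <- function(Pr, Rc) {
  if (is.nan(Pr) || is.nan(Rc)) return(NaN)
  if (Pr + Rc == 0) {
    warning("F1 undefined (Pr + Rc = 0); reported as NaN")
    return(NaN)
  }
  2 * Pr * Rc / (Pr + Rc)
}

#' Render a fraction as a percent string, half-up to 1 decimal
#'
#' @param x numeric fractions.
#' @return character vector like \code{"83.7\%"}.
#' @export
formatPercent <- function(x) {
  # round half up at 1 dp (standard table formatting)
  sprintf("%.1f%%", floor(x * 1000 + 0.5) / 10)
}

#' Evaluate a model or ensemble on a labeled test set
#'
#' @param probs predicted probabilities.
#' @param labels true binary labels.
#' @param threshold classification threshold.
#' @return Named numeric vector from [computeMetrics()].
#' @export
evaluateProbs <- function(probs, labels, threshold = 0.5) {
  computeMetrics(confusionCounts(labels, as.integer(probs >= threshold)))
}
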