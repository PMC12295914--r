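#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues in the fixed order that defines the integer
#' encoding (index 1..20); index 0 is reserved for padding/masking.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Integer encoding specification for peptides
#'
#' Maps the 20 standard residues to indices 1..20 (order of
#' [AA_ALPHABET20]) with 0 as the padding/masking index, and fixes the
#' encoded length. Peptides shorter than \code{maxLen} are right-padded;
#' longer peptides are an error unless truncation is requested at encode
#' time.
#'
#' @slot alphabet character vector of the 20 residues in index order.
#' @slot maxLen single integer, the encoded (padded) length.
#' @export
setClass("EncodingSpec",
  representation(alphabet = "character", maxLen = "integer"),
  prototype(alphabet = AA_ALPHABET20, maxLen = 20L),
  validity = function(object) {
    if (length(object@alphabet) != 20L ||
        anyDuplicated(object@alphabet))
      return("alphabet must be 20 distinct residue letters")
    if (length(object@maxLen) != 1L || is.na(object@maxLen) ||
        object@maxLen < 1L)
      return("maxLen must be a positive integer")
    TRUE
  })

#' Construct an EncodingSpec
#'
#' @param maxLen encoded (padded) peptide length; peptides longer than
#'   this cannot be encoded without truncation.
#' @return An [EncodingSpec-class] object.
#' @examples
#' spec <- encodingSpec(maxLen = 12)
#' @export
encodingSpec <- function(maxLen = 20L) {
  new("EncodingSpec", alphabet = AA_ALPHABET20,
      maxLen = as.integer(maxLen))
}

#' A trained sub-model of the umami ensemble
#'
#' Wraps the parameters of one of the four sequence classifiers
#' (\code{"cnn"}, \code{"lstm"}, \code{"attention"},
#' \code{"transformer"}) together with its configuration, the encoding
#' it was trained with, and its training history. Inference is
#' deterministic: identical parameters and input always give the same
#' probability.
#'
#' @slot kind one of \code{"cnn"}, \code{"lstm"}, \code{"attention"},
#'   \code{"transformer"}.
#' @slot config named list of hyperparameters (includes the seed).
#' @slot params named list of numeric parameter arrays.
#' @slot encoding the [EncodingSpec-class] used for training.
#' @slot history data.frame of per-epoch training/validation loss.
#' @export
setClass("UmamiSubModel",
  representation(kind = "character", config = "list", params = "list",
                 encoding = "EncodingSpec", history = "data.frame"),
  validity = function(object) {
    if (!object@kind %in% c("cnn", "lstm", "attention", "transformer"))
      return("kind must be cnn, lstm, attention or transformer")
    TRUE
  })

#' A four-model unanimity ensemble
#'
#' Holds exactly one trained sub-model of each kind plus the per-model
#' decision threshold. A peptide is called umami only when every
#' sub-model's probability reaches the threshold (unanimity vote);
#' candidates are ranked by the arithmetic mean of the four
#' probabilities.
#'
#' @slot models named list of four [UmamiSubModel-class] objects, one
#'   per kind.
#' @slot threshold per-sub-model decision threshold (default 0.5).
#' @export
setClass("UmamiEnsemble",
  representation(models = "list", threshold = "numeric"),
  validity = function(object) {
    kinds <- vapply(object@models, function(m) m@kind, character(1))
    if (length(object@models) != 4L ||
        !setequal(kinds, c("cnn", "lstm", "attention", "transformer")))
      return("ensemble needs exactly four models, one per kind")
    if (length(object@threshold) != 1L || object@threshold <= 0 ||
        object@threshold >= 1)
      return("threshold must be in (0, 1)")
    TRUE
  })

#' Position-wise Shapley attribution of a peptide prediction
#'
#' One Shapley value per peptide position (players are positions;
#' an absent position is replaced by the padding index). In exact mode
#' the efficiency axiom holds: \code{baseValue + sum(values)} equals the
#' model output on the full peptide to numerical precision; in sampled
#' mode it holds up to Monte-Carlo error.
#'
#' @slot sequence the peptide explained.
#' @slot values named numeric vector \code{Pos_0..Pos_{L-1}}.
#' @slot baseValue model output with every position masked.
#' @slot prediction model output on the full peptide.
#' @slot mode \code{"exact"} or \code{"sampled"}.
#' @slot nSamples number of sampled permutations (0 in exact mode).
#' @slot seed RNG seed used in sampled mode (NA in exact mode).
#' @export
setClass("PositionAttribution",
  representation(sequence = "character", values = "numeric",
                 baseValue = "numeric", prediction = "numeric",
                 mode = "character", nSamples = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (!object@mode %in% c("exact", "sampled"))
      return("mode must be 'exact' or 'sampled'")
    if (length(object@values) != nchar(object@sequence))
      return("one value per peptide position required")
    if (!all(is.finite(object@values)))
      return("attribution values must be finite")
    TRUE
  })

setMethod("show", "EncodingSpec", function(object) {
  cat("EncodingSpec: 20 residues -> 1..20, pad = 0, maxLen =",
      object@maxLen, "\n")
})

setMethod("show", "UmamiSubModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("UmamiSubModel <%s>: %d parameters, maxLen %d, seed %s\n",
              object@kind, np, object@encoding@maxLen,
              as.character(object@config$seed)))
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs, best val loss %.4f\n",
                max(object@history$epoch),
                min(object@history$val_loss)))
})

setMethod("show", "UmamiEnsemble", function(object) {
  cat(sprintf(
    "UmamiEnsemble: cnn + lstm + attention + transformer, threshold %.2f\n",
    object@threshold))
})

setMethod("show", "PositionAttribution", function(object) {
  cat(sprintf("PositionAttribution [%s] for %s\n", object@mode,
              object@sequence))
  cat(sprintf("  base %.4f -> prediction %.4f (sum of values %.4f)\n",
              object@baseValue, object@prediction, sum(object@values)))
  print(round(object@values, 4))
})
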