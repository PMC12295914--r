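#' Load a labeled peptide corpus from CSV
#'
#' Expects columns \code{sequence} and \code{label} (binary 0/1; 1 =
#' umami) and optionally \code{source}. Sequences are upper-cased and
#' checked against the 20-letter alphabet; exact duplicate
#' (sequence, label) rows are dropped with a message.
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{sequence}, \code{label},
#'   \code{source}.
#' @export
loadLabeledPeptides <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "label") %in% names(df)))
    stop("CSV must have columns 'sequence' and 'label'")
  df$sequence <- toupper(trimws(df$sequence))
  if (any(nchar(df$sequence) == 0L)) stop("empty sequence in corpus")
  if (!all(df$label %in% c(0L, 1L)))
    stop("labels must be binary 0/1; found: ",
         paste(unique(df$label[!df$label %in% c(0, 1)]), collapse = ", "))
  .checkAAAlphabet(df$sequence, what = "corpus row")
  if (is.null(df$source)) df$source <- ""
  dup <- duplicated(df[c("sequence", "label")])
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicate labeled rows")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[c("sequence", "label", "source")]
}

#' Balance a two-class corpus with strict redundancy removal
#'
#' Removes exact duplicates within each class, drops entirely any
#' sequence that appears with both labels (logged), then downsamples
#' the larger class to the size of the smaller with a seeded sampler so
#' the result is a 1:1 balanced corpus.
#'
#' @param pos,neg character vectors (or data.frames with a
#'   \code{sequence} column) of positive / negative peptides.
#' @param seed integer seed for the downsampling.
#' @return data.frame with columns \code{sequence}, \code{label}.
#' @export
balanceCorpus <- function(pos, neg, seed = 1L) {
  if (is.data.frame(pos)) pos <- pos$sequence
  if (is.data.frame(neg)) neg <- neg$sequence
  pos <- unique(toupper(pos)); neg <- unique(toupper(neg))
  conflict <- intersect(pos, neg)
  if (length(conflict)) {
    message("dropping ", length(conflict),
            " sequences present in both classes")
    pos <- setdiff(pos, conflict)
    neg <- setdiff(neg, conflict)
  }
  if (!length(pos) || !length(neg))
    stop("a class is empty after redundancy removal")
  n <- min(length(pos), length(neg))
  rng <- .localSeed(seed)
  on.exit(rng())
  if (length(pos) > n) pos <- sort(sample(pos, n))
  if (length(neg) > n) neg <- sort(sample(neg, n))
  data.frame(sequence = c(pos, neg),
             label = rep(c(1L, 0L), c(length(pos), length(neg))),
             stringsAsFactors = FALSE)
}

#' Stratified reproducible train/test split
#'
#' Per class, \code{round(trainFraction * classSize)} records go to
#' training (floor plus remainder assigned to train), the rest to test;
#' the partition is disjoint, exhaustive, and identical for identical
#' seeds.
#'
#' @param corpus data.frame with \code{sequence} and \code{label}.
#' @param trainFraction fraction in (0, 1); default 0.8.
#' @param seed integer RNG seed.
#' @param stratified split within each label (default) or plain random.
#' @return list with data.frames \code{train} and \code{test}.
#' @examples
#' corpus <- syntheticCorpus(20, seed = 1)
#' sp <- splitCorpus(corpus, 0.8, seed = 7)
#' nrow(sp$train); nrow(sp$test)
#' @export
splitCorpus <- function(corpus, trainFraction = 0.8, seed = 1L,
                        stratified = TRUE) {
  stopifnot(trainFraction > 0, trainFraction < 1,
            nrow(corpus) >= 10L)
  rng <- .localSeed(seed)
  on.exit(rng())
  groups <- if (stratified) split(seq_len(nrow(corpus)), corpus$label)
            else list(seq_len(nrow(corpus)))
  trainIdx <- integer()
  for (idx in groups) {
    k <- round(trainFraction * length(idx))
    if (k == 0L || k == length(idx))
      stop("trainFraction yields an empty split side for a class")
    trainIdx <- c(trainIdx, sample(idx, k))
  }
  trainIdx <- sort(trainIdx)
  list(train = corpus[trainIdx, , drop = FALSE],
       test = corpus[setdiff(seq_len(nrow(corpus)), trainIdx), ,
                     drop = FALSE])
}

#' Write a train/test split manifest as JSON for provenance
#'
#' Records the split sequences, labels and parameters so a split can
#' be audited or reproduced later.
#'
#' @param split result of [splitCorpus()].
#' @param path output JSON path.
#' @param seed,trainFraction the parameters used to create the split.
#' @return Invisibly, \code{path}.
#' @export
writeSplitManifest <- function(split, path, seed = NA_integer_,
                               trainFraction = NA_real_) {
  jsonlite::write_json(
    list(seed = seed, train_fraction = trainFraction,
         n_train = nrow(split$train), n_test = nrow(split$test),
         train = split$train[c("sequence", "label")],
         test = split$test[c("sequence", "label")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Seed the RNG locally; returns a restore function for on.exit().
.localSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
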