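#' Global-alignment sequence identity, shorter-sequence denominator
#'
#' Aligns two peptides with Needleman-Wunsch scoring match = 1,
#' mismatch = 0, gap = -1, counts the identical aligned residue pairs
#' on a deterministic (diagonal-preferring) traceback, and divides by
#' the length of the shorter sequence — the convention greedy identity
#' clustering tools use for global identity.
#'
#' @param a,b non-empty peptide strings.
#' @return Identity fraction in \[0, 1\]; symmetric in its arguments.
#' @examples
#' pairwiseIdentity("AAAAAAAAAV", "AAAAAAAAAA")  # 0.9
#' @export
pairwiseIdentity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  ## score DP, gap -1, match 1, mismatch 0
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- -(0:n)
  S[1L, ] <- -(0:m)
  for (i in seq_len(n)) {
    mi <- as.numeric(x[i] == y)          # match bonus along row
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + mi[j],
                               S[i, j + 1L] - 1,
                               S[i + 1L, j] - 1)
    }
  }
  ## traceback preferring diagonal, then up, then left
  i <- n; j <- m; matches <- 0L
  while (i > 0L && j > 0L) {
    diag <- S[i, j] + (x[i] == y[j])
    if (S[i + 1L, j + 1L] == diag) {
      if (x[i] == y[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (S[i + 1L, j + 1L] == S[i, j + 1L] - 1) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  matches / min(n, m)
}

#' Greedy longest-first identity clustering of peptides
#'
#' CD-HIT-style redundancy removal at desk scale: peptides are sorted
#' by length descending (ties broken lexicographically), then each
#' peptide joins the first existing cluster whose representative it
#' matches at \code{>= threshold} identity (per [pairwiseIdentity()]),
#' or founds a new cluster. The ordering makes the result fully
#' deterministic without any seed; representatives are never shorter
#' than their members.
#'
#' @param peptides character vector of peptide sequences (duplicates
#'   allowed; exact duplicates always co-cluster).
#' @param threshold identity threshold in (0, 1\]; default 0.9.
#' @return A list with \code{representatives} (character vector in
#'   founding order) and \code{clusters} (data.frame with columns
#'   \code{member}, \code{cluster} (1-based representative index),
#'   \code{representative}, \code{identity}).
#' @examples
#' clusterPeptides(c("AAAAAAAAAA", "AAAAAAAAAV", "WWWWWWWWWW"))
#' @export
clusterPeptides <- function(peptides, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(peptides) == 0L)
    return(list(representatives = character(),
                clusters = data.frame(member = character(),
                                      cluster = integer(),
                                      representative = character(),
                                      identity = numeric())))
  ord <- order(-nchar(peptides), peptides)
  sorted <- peptides[ord]
  reps <- character()
  assign <- integer(length(sorted))
  ident <- numeric(length(sorted))
  for (i in seq_along(sorted)) {
    s <- sorted[[i]]
    hit <- 0L
    for (k in seq_along(reps)) {
      idk <- if (reps[[k]] == s) 1 else pairwiseIdentity(reps[[k]], s)
      if (idk >= threshold) { hit <- k; ident[i] <- idk; break }
    }
    if (hit == 0L) {
      reps <- c(reps, s)
      hit <- length(reps)
      ident[i] <- 1
    }
    assign[i] <- hit
  }
  list(representatives = reps,
       clusters = data.frame(member = sorted, cluster = assign,
                             representative = reps[assign],
                             identity = ident,
                             stringsAsFactors = FALSE))
}

#' Write a clustering result as representatives FASTA + cluster report
#'
#' @param clustering result of [clusterPeptides()].
#' @param fastaPath output FASTA of representatives.
#' @param reportPath output TSV cluster report (member, cluster,
#'   representative, identity).
#' @return Invisibly, \code{fastaPath}.
#' @export
writeClusters <- function(clustering, fastaPath, reportPath = NULL) {
  reps <- Biostrings::AAStringSet(clustering$representatives)
  names(reps) <- sprintf("cluster%d", seq_along(reps))
  Biostrings::writeXStringSet(reps, fastaPath)
  if (!is.null(reportPath))
    utils::write.table(clustering$clusters, reportPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(fastaPath)
}
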