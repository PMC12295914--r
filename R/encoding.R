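#' Encode peptides as fixed-length integer index matrices
#'
#' Residues map to indices 1..20 in the order of [AA_ALPHABET20];
#' sequences are left-aligned and right-padded with the pad index 0.
#' The encoding is invertible up to padding via [decodePeptides()].
#'
#' @param peptides character vector of peptides.
#' @param spec an [encodingSpec()].
#' @param truncate if TRUE, peptides longer than \code{maxLen} are
#'   truncated with a warning; if FALSE (default) they are an error.
#' @return Integer matrix \[n, maxLen\] with rownames the peptides.
#' @examples
#' encodePeptides("A", encodingSpec(4))   # 1 0 0 0
#' @export
encodePeptides <- function(peptides, spec = encodingSpec(),
                           truncate = FALSE) {
  .checkAAAlphabet(peptides, what = "peptide")
  L <- spec@maxLen
  long <- nchar(peptides) > L
  if (any(long)) {
    if (!truncate)
      stop(sum(long), " peptide(s) longer than maxLen = ", L,
           " (first: '", peptides[long][1], "')")
    warning("truncating ", sum(long), " peptide(s) to maxLen = ", L)
    peptides[long] <- substr(peptides[long], 1L, L)
  }
  lookup <- seq_len(20L)
  names(lookup) <- spec@alphabet
  X <- matrix(0L, length(peptides), L)
  for (i in seq_along(peptides)) {
    res <- strsplit(peptides[[i]], "")[[1]]
    X[i, seq_along(res)] <- lookup[res]
  }
  rownames(X) <- peptides
  X
}

#' @rdname encodePeptides
#' @param X integer matrix from [encodePeptides()].
#' @return \code{decodePeptides}: the character vector of peptides.
#' @export
decodePeptides <- function(X, spec = encodingSpec()) {
  apply(X, 1L, function(row) {
    row <- row[row != 0L]
    paste(spec@alphabet[row], collapse = "")
  })
}
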