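#' Read and validate a nucleotide FASTA file
#'
#' Reads a FASTA file of contigs/reads, upper-cases the sequences and
#' checks them against the \code{{A,C,G,T,N}} alphabet. Any other
#' character is an error naming the record and the 1-based offending
#' position.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per record,
#'   names taken from the header up to the first whitespace, with the
#'   full header kept in \code{mcols()$description}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a toy", "acg", "t"), fa)
#' readNucleotideFasta(fa)
#' @export
readNucleotideFasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stop("no FASTA records in ", path)
  seqs <- toupper(as.character(raw))
  full <- names(raw)
  ids <- sub("\\s.*$", "", full)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) == 0L)
      stop("record '", ids[[i]], "' has an empty sequence")
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L)
      stop("record '", ids[[i]], "': illegal character '",
           substr(seqs[[i]], bad, bad), "' at position ", bad)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- full
  out
}

#' Write protein records (e.g. ORFs) to FASTA
#'
#' Headers follow the \code{parentid|frame|start-end} convention when
#' the ORF metadata columns are present, otherwise the element names
#' are used.
#'
#' @param aa an [Biostrings::AAStringSet], typically from [findOrfs()].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeProteinFasta <- function(aa, path) {
  mc <- S4Vectors::mcols(aa)
  if (!is.null(mc) && all(c("parent_id", "frame", "start_nt", "end_nt")
                          %in% colnames(mc))) {
    names(aa) <- sprintf("%s|%+d|%d-%d", mc$parent_id, mc$frame,
                         mc$start_nt, mc$end_nt)
  }
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# validate a vector of peptide/protein strings against the 20-letter
# alphabet (optionally allowing X); errors name sequence and position
.checkAAAlphabet <- function(seqs, allowX = FALSE, what = "sequence") {
  pat <- if (allowX) "[^ACDEFGHIKLMNPQRSTVWYX]" else
    "[^ACDEFGHIKLMNPQRSTVWY]"
  for (i in seq_along(seqs)) {
    bad <- regexpr(pat, seqs[[i]])
    if (bad > 0L)
      stop(what, " ", i, " ('", seqs[[i]], "'): illegal residue '",
           substr(seqs[[i]], bad, bad), "' at position ", bad)
  }
  invisible(TRUE)
}
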