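#' Six-frame open reading frame extraction
#'
#' Emulates the classic "translation between stop codons" ORF
#' definition: in each of the six reading frames, every maximal run of
#' codons uninterrupted by a stop codon (bounded by stop codons or the
#' sequence ends) whose nucleotide length is at least \code{minLenNt}
#' is translated and emitted. Codons containing \code{N} translate to
#' \code{X}. Reverse-strand ORFs are reported with 0-based half-open
#' coordinates on the forward strand.
#'
#' @param dna a [Biostrings::DNAStringSet] (e.g. from
#'   [readNucleotideFasta()]) or a single character string.
#' @param minLenNt minimum ORF length in nucleotides (excluding the
#'   stop codon); must be a positive multiple of 3. Default 30, the
#'   conventional ORF-finder minimum.
#' @return An [Biostrings::AAStringSet] of ORF translations with
#'   metadata columns \code{parent_id}, \code{frame} (one of +1, +2,
#'   +3, -1, -2, -3), \code{start_nt}, \code{end_nt} (0-based half-open
#'   forward-strand coordinates). Output order is deterministic: by
#'   record, then frame (+1..+3, -1..-3), then position.
#' @examples
#' orfs <- findOrfs(Biostrings::DNAStringSet(c(x = "ATGAAATAA")),
#'                  minLenNt = 6)
#' as.character(orfs)   # "MK"
#' @export
findOrfs <- function(dna, minLenNt = 30L) {
  if (is.character(dna))
    dna <- Biostrings::DNAStringSet(setNames(dna, seq_along(dna)))
  minLenNt <- as.integer(minLenNt)
  if (minLenNt < 3L || minLenNt %% 3L != 0L)
    stop("minLenNt must be a positive multiple of 3")
  ids <- names(dna)
  if (is.null(ids)) ids <- as.character(seq_along(dna))
  res <- list()
  for (r in seq_along(dna)) {
    fwd <- as.character(dna[[r]])
    L <- nchar(fwd)
    rev <- as.character(Biostrings::reverseComplement(dna[[r]]))
    for (strand in c(1L, -1L)) {
      s <- if (strand > 0L) fwd else rev
      for (off in 0:2) {
        orfs <- .frameOrfs(s, off, minLenNt)
        if (!nrow(orfs)) next
        if (strand > 0L) {
          start_nt <- orfs$start; end_nt <- orfs$end
        } else {
          start_nt <- L - orfs$end; end_nt <- L - orfs$start
        }
        res[[length(res) + 1L]] <- data.frame(
          protein = orfs$protein, parent_id = ids[[r]],
          frame = strand * (off + 1L),
          start_nt = start_nt, end_nt = end_nt,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(res)) do.call(rbind, res) else
    data.frame(protein = character(), parent_id = character(),
               frame = integer(), start_nt = integer(),
               end_nt = integer())
  out <- Biostrings::AAStringSet(tab$protein)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    parent_id = tab$parent_id, frame = tab$frame,
    start_nt = tab$start_nt, end_nt = tab$end_nt)
  out
}

# ORFs of one frame of one (already strand-resolved) sequence.
# Returns 0-based half-open coordinates local to that strand.
.frameOrfs <- function(seq, off, minLenNt) {
  L <- nchar(seq)
  ncod <- (L - off) %/% 3L
  if (ncod < 1L)
    return(data.frame(protein = character(), start = integer(),
                      end = integer()))
  starts <- off + 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(seq, starts, starts + 2L)
  aa <- .translateCodons(codons)
  isStop <- aa == "*"
  runs <- rle(!isStop)
  endIdx <- cumsum(runs$lengths)
  startIdx <- endIdx - runs$lengths + 1L
  keep <- runs$values & (3L * runs$lengths >= minLenNt)
  if (!any(keep))
    return(data.frame(protein = character(), start = integer(),
                      end = integer()))
  i0 <- startIdx[keep]; i1 <- endIdx[keep]
  data.frame(
    protein = vapply(seq_along(i0), function(k)
      paste(aa[i0[k]:i1[k]], collapse = ""), character(1)),
    start = off + 3L * (i0 - 1L),
    end = off + 3L * i1)
}

# standard genetic code; any codon containing N (or otherwise absent
# from the table) translates to X
.translateCodons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  aa
}

#' Translate a nucleotide region of a record
#'
#' Helper mainly used to verify coordinate round-trips: translates
#' \code{substr(seq, start+1, end)} (reverse-complemented first when
#' \code{frame < 0}) with the standard code, N-codons to X.
#'
#' @param seq forward-strand nucleotide string.
#' @param start,end 0-based half-open forward-strand coordinates.
#' @param frame signed frame; only the sign is used.
#' @return The translated protein string (stops as \code{*}).
#' @export
translateRegion <- function(seq, start, end, frame = 1L) {
  sub <- substr(seq, start + 1L, end)
  if (frame < 0L)
    sub <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(sub)))
  n <- nchar(sub) %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  paste(.translateCodons(substring(sub, starts, starts + 2L)),
        collapse = "")
}
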