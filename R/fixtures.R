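# Synthetic data generators: a labeled peptide corpus with a planted
# N-terminal acidic signal (umami-like peptides are rich in D/E near
# the N-terminus), and a toy "genome" with peptides planted inside
# ORFs so the ORF + digestion stages recover them exactly.

#' Synthetic labeled peptide corpus with a planted positional signal
#'
#' Positive peptides draw each of their first \code{k} positions from
#' \{D, E\} with probability \code{pDE} and from the remaining 18
#' residues otherwise, so the acidic rate at signal positions is
#' exactly \code{pDE}; negatives are uniform background, whose
#' acidic rate is 2/20 = 0.1. This emulates the acidic N-terminal
#' enrichment of umami peptides: the signal lives in the first
#' \code{k} positions, so a faithful classifier and a faithful
#' attribution method must both point there. With \code{pDE} equal to
#' the background rate 0.1 the classes are indistinguishable by
#' construction.
#'
#' @param nPerClass peptides per class.
#' @param lenRange length range (uniform), default 5..12; minimum at
#'   least \code{k}.
#' @param k number of signal positions (default 3).
#' @param pDE per-position probability of drawing from \{D, E\} in
#'   positives (default 0.8).
#' @param seed integer seed; identical seeds give identical corpora.
#' @param maxTries resampling attempts to avoid cross-label duplicate
#'   sequences before giving up.
#' @return data.frame with columns \code{sequence}, \code{label}
#'   (1 = signal class first), \code{source}.
#' @examples
#' head(syntheticCorpus(5, seed = 1))
#' @export
syntheticCorpus <- function(nPerClass, lenRange = c(5L, 12L), k = 3L,
                            pDE = 0.8, seed = 1L, maxTries = 50L) {
  stopifnot(nPerClass > 0, pDE >= 0, pDE <= 1, k >= 1,
            lenRange[1] >= k, lenRange[2] >= lenRange[1])
  restore <- .localSeed(seed)
  on.exit(restore())
  nonAcidic <- setdiff(AA_ALPHABET20, c("D", "E"))
  drawPeptide <- function(signal) {
    L <- sample(lenRange[1]:lenRange[2], 1L)
    res <- sample(AA_ALPHABET20, L, replace = TRUE)
    if (signal)
      for (j in seq_len(k))
        res[j] <- if (stats::runif(1) < pDE)
          sample(c("D", "E"), 1L) else sample(nonAcidic, 1L)
    paste(res, collapse = "")
  }
  pos <- vapply(seq_len(nPerClass), function(i) drawPeptide(TRUE),
                character(1))
  neg <- vapply(seq_len(nPerClass), function(i) drawPeptide(FALSE),
                character(1))
  for (tr in seq_len(maxTries)) {
    clash <- which(neg %in% pos)
    if (!length(clash)) break
    if (tr == maxTries)
      stop("could not generate a conflict-free corpus; ",
           "spec infeasible (lengths too short for nPerClass)")
    neg[clash] <- vapply(clash, function(i) drawPeptide(FALSE),
                         character(1))
  }
  data.frame(sequence = c(pos, neg),
             label = rep(c(1L, 0L), each = nPerClass),
             source = "synthetic", stringsAsFactors = FALSE)
}

# degenerate codon table for seeded reverse translation
.CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"),
  F = c("TTT", "TTC"), G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  K = c("AAA", "AAG"), L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  M = "ATG", N = c("AAT", "AAC"),
  P = c("CCT", "CCC", "CCA", "CCG"), Q = c("CAA", "CAG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG", Y = c("TAT", "TAC"))

.reverseTranslate <- function(protein) {
  paste(vapply(strsplit(protein, "")[[1]], function(r) {
    cods <- .CODONS[[r]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

#' Toy genome with planted, digestion-recoverable peptides
#'
#' Each peptide is reverse-translated (seeded random synonymous
#' codons) and embedded at the C-terminus of a small ORF of the form
#' \code{M + filler + K + peptide}, flanked by stop-rich spacers, so
#' that six-frame ORF extraction followed by combined
#' trypsin/chymotrypsin digestion emits the peptide exactly: the K
#' before it is a tryptic cut and the ORF end terminates it.
#'
#' Peptides must be compatible with recovery: no internal cleavage
#' sites beyond \code{maxMissed} under \code{rules}, and not starting
#' with P (which would block the upstream tryptic cut).
#'
#' @param peptides character vector to plant (may be empty).
#' @param seed integer seed for codon choice and filler.
#' @param spacerCodons stop codons between ORFs (default 4).
#' @param rules digestion rules used for the compatibility check.
#' @param maxMissed missed cleavages assumed available downstream.
#' @return A single-record [Biostrings::DNAStringSet] named
#'   \code{synthetic_genome}.
#' @examples
#' g <- plantedGenome("DDSMAATGL", seed = 7)
#' @export
plantedGenome <- function(peptides, seed = 1L, spacerCodons = 4L,
                          rules = list(enzymePreset("trypsin"),
                                       enzymePreset("chymotrypsin-high")),
                          maxMissed = 0L) {
  restore <- .localSeed(seed)
  on.exit(restore())
  for (p in peptides) {
    .checkAAAlphabet(p, what = "planted peptide")
    if (substr(p, 1L, 1L) == "P")
      stop("peptide '", p, "' starts with P: blocks the upstream cut")
    ncuts <- length(cleavageSites(p, rules))
    if (ncuts > maxMissed)
      stop("peptide '", p, "' has ", ncuts, " internal cleavage site(s);",
           " not recoverable with maxMissed = ", maxMissed)
  }
  stops <- c("TAA", "TAG", "TGA")
  spacer <- function() paste(sample(stops, spacerCodons, replace = TRUE),
                             collapse = "")
  chunks <- spacer()
  for (p in peptides) {
    filler <- paste(sample(c("A", "G", "S", "T", "V"), 3L,
                           replace = TRUE), collapse = "")
    orf <- paste0("M", filler, "K", p)
    chunks <- paste0(chunks, .reverseTranslate(orf), spacer())
  }
  out <- Biostrings::DNAStringSet(chunks)
  names(out) <- "synthetic_genome"
  out
}
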