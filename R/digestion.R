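#' Proteolytic cleavage rules
#'
#' A cleavage rule fires C-terminal to any residue in
#' \code{cleaveAfter} unless the next residue is in
#' \code{blockedByNext} (the classic proline exception). Presets follow
#' the PeptideCutter conventions: trypsin cuts after K/R, chymotrypsin
#' (high specificity) after F/W/Y, chymotrypsin (low specificity) also
#' after L/M; all are blocked by a following P.
#'
#' @param name rule name.
#' @param cleaveAfter residues cut C-terminally.
#' @param blockedByNext residues that block the cut when immediately
#'   downstream.
#' @return A \code{cleavage_rule} list.
#' @examples
#' cleavageRule("trypsin", c("K", "R"), "P")
#' enzymePreset("chymotrypsin-high")
#' @export
cleavageRule <- function(name, cleaveAfter, blockedByNext = character()) {
  cleaveAfter <- unique(toupper(cleaveAfter))
  blockedByNext <- unique(toupper(blockedByNext))
  stopifnot(length(cleaveAfter) > 0L,
            all(cleaveAfter %in% AA_ALPHABET20),
            all(blockedByNext %in% AA_ALPHABET20))
  structure(list(name = name, cleaveAfter = cleaveAfter,
                 blockedByNext = blockedByNext),
            class = "cleavage_rule")
}

#' @rdname cleavageRule
#' @param preset one of \code{"trypsin"}, \code{"chymotrypsin-high"},
#'   \code{"chymotrypsin-low"}.
#' @export
enzymePreset <- function(preset = c("trypsin", "chymotrypsin-high",
                                    "chymotrypsin-low")) {
  preset <- match.arg(preset)
  switch(preset,
    "trypsin" = cleavageRule("trypsin", c("K", "R"), "P"),
    "chymotrypsin-high" = cleavageRule("chymotrypsin-high",
                                       c("F", "W", "Y"), "P"),
    "chymotrypsin-low" = cleavageRule("chymotrypsin-low",
                                      c("F", "W", "Y", "L", "M"), "P"))
}

#' Digestion parameters
#'
#' @param rules list of [cleavageRule()] objects (default: combined
#'   trypsin + high-specificity chymotrypsin, applied simultaneously as
#'   a union of cut sites).
#' @param maxMissedCleavages non-negative integer; \code{m} missed
#'   cleavages allow concatenating up to \code{m + 1} adjacent
#'   fragments.
#' @param minLenAa,maxLenAa peptide length window kept after digestion.
#' @return A \code{digest_params} list.
#' @export
digestParams <- function(rules = list(enzymePreset("trypsin"),
                                      enzymePreset("chymotrypsin-high")),
                         maxMissedCleavages = 0L,
                         minLenAa = 4L, maxLenAa = 15L) {
  if (inherits(rules, "cleavage_rule")) rules <- list(rules)
  stopifnot(length(rules) > 0L,
            all(vapply(rules, inherits, logical(1), "cleavage_rule")),
            maxMissedCleavages >= 0L, minLenAa >= 1L,
            maxLenAa >= minLenAa)
  structure(list(rules = rules,
                 maxMissedCleavages = as.integer(maxMissedCleavages),
                 minLenAa = as.integer(minLenAa),
                 maxLenAa = as.integer(maxLenAa)),
            class = "digest_params")
}

#' Cut positions of a protein under a set of cleavage rules
#'
#' A cut position \code{p} means the bond between residues \code{p} and
#' \code{p + 1} (1-based residues; equivalently the 0-based half-open
#' boundary at \code{p}) is hydrolysed. The union over rules is
#' returned, deduplicated and ascending. The C-terminal residue has no
#' downstream bond and therefore never yields a cut.
#'
#' @param protein a protein/peptide string.
#' @param rules a list of [cleavageRule()] objects (or a single rule).
#' @return Sorted integer vector of cut positions in
#'   \code{1..nchar(protein) - 1}.
#' @examples
#' cleavageSites("MKAYR", list(enzymePreset("trypsin"),
#'                             enzymePreset("chymotrypsin-high")))
#' @export
cleavageSites <- function(protein, rules) {
  if (inherits(rules, "cleavage_rule")) rules <- list(rules)
  n <- nchar(protein)
  if (n == 0L) stop("empty protein")
  if (n == 1L) return(integer())
  res <- strsplit(protein, "")[[1]]
  cuts <- integer()
  for (rule in rules) {
    p <- which(res[-n] %in% rule$cleaveAfter)
    p <- p[!res[p + 1L] %in% rule$blockedByNext]
    cuts <- c(cuts, p)
  }
  sort(unique(cuts))
}

#' In-silico digestion of one protein
#'
#' Fragments are the stretches between consecutive cut sites (and the
#' termini); with \code{maxMissedCleavages = m} every concatenation of
#' up to \code{m + 1} adjacent fragments is also emitted. Peptides are
#' then length-filtered and any peptide containing \code{X} (from
#' ambiguous codons upstream) is dropped. Order is deterministic by
#' (start, end).
#'
#' @param protein protein string (may contain X).
#' @param params a [digestParams()] object.
#' @param parentId identifier copied to the output.
#' @return data.frame with columns \code{sequence}, \code{parent_id},
#'   \code{start_aa}, \code{end_aa} (0-based half-open on the parent),
#'   \code{missed_cleavages}.
#' @examples
#' digestProtein("MKAYR", digestParams(minLenAa = 2, maxLenAa = 10))
#' @export
digestProtein <- function(protein, params = digestParams(),
                          parentId = "protein") {
  stopifnot(inherits(params, "digest_params"))
  n <- nchar(protein)
  if (n == 0L) stop("empty protein")
  cuts <- cleavageSites(protein, params$rules)
  bounds <- c(0L, cuts, n)                   # 0-based fragment bounds
  nf <- length(bounds) - 1L
  starts <- integer(); ends <- integer(); missed <- integer()
  for (w in seq_len(min(params$maxMissedCleavages + 1L, nf))) {
    i <- seq_len(nf - w + 1L)
    starts <- c(starts, bounds[i])
    ends <- c(ends, bounds[i + w])
    missed <- c(missed, rep(w - 1L, length(i)))
  }
  len <- ends - starts
  keep <- len >= params$minLenAa & len <= params$maxLenAa
  seqs <- substring(protein, starts + 1L, ends)
  keep <- keep & !grepl("X", seqs, fixed = TRUE)
  out <- data.frame(sequence = seqs[keep],
                    parent_id = rep(parentId, sum(keep)),
                    start_aa = starts[keep], end_aa = ends[keep],
                    missed_cleavages = missed[keep],
                    stringsAsFactors = FALSE)
  out[order(out$start_aa, out$end_aa), , drop = FALSE]
}

#' Digest a set of proteins
#'
#' @param proteins an [Biostrings::AAStringSet] (e.g. from
#'   [findOrfs()]) or named character vector.
#' @inheritParams digestProtein
#' @return Row-bound data.frame of [digestProtein()] results, one block
#'   per protein in input order.
#' @export
digestProteins <- function(proteins, params = digestParams()) {
  ids <- names(proteins)
  seqs <- as.character(proteins)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  parts <- lapply(seq_along(seqs), function(i)
    digestProtein(seqs[[i]], params, parentId = ids[[i]]))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
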