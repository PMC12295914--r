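# Shared independent oracles and cached fixtures for the test suite.
# Oracles deliberately use different code paths (Biostrings translate /
# alignment, direct enumeration) than the package implementation.

# six-frame ORF oracle: translate whole frames with Biostrings, split
# on stops, keep runs >= minLenNt
oracleOrfs <- function(seqStr, minLenNt) {
  out <- list()
  L <- nchar(seqStr)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seqStr)))
  for (strand in c(1L, -1L)) {
    s <- if (strand > 0) seqStr else rc
    for (off in 0:2) {
      ncod <- (L - off) %/% 3
      if (ncod < 1) next
      sub <- substr(s, off + 1, off + 3 * ncod)
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X",
        no.init.codon = TRUE))
      # runs between stops
      pieces <- strsplit(aa, "*", fixed = TRUE)[[1]]
      pos <- 0L
      for (p in pieces) {
        if (nchar(p) >= minLenNt / 3)
          out[[length(out) + 1L]] <- list(
            protein = p, frame = strand * (off + 1L),
            startCodon = pos)
        pos <- pos + nchar(p) + 1L
      }
    }
  }
  out
}

# brute-force digestion oracle: enumerate every substring and keep the
# ones whose boundaries are termini-or-cuts and whose interior has at
# most maxMissed cuts
oracleDigest <- function(protein, rules, maxMissed, minLen, maxLen) {
  n <- nchar(protein)
  res <- strsplit(protein, "")[[1]]
  isCut <- function(p) {     # bond after residue p (1-based), p < n
    any(vapply(rules, function(r)
      res[p] %in% r$cleaveAfter && !(res[p + 1] %in% r$blockedByNext),
      logical(1)))
  }
  cuts <- Filter(isCut, seq_len(max(0, n - 1)))
  bounds <- c(0L, cuts, n)
  out <- character()
  for (i in seq_len(n)) for (j in i:n) {
    s <- i - 1L; e <- j          # 0-based half-open
    if (!(s %in% bounds) || !(e %in% bounds)) next
    interior <- sum(cuts > s & cuts < e)
    if (interior > maxMissed) next
    len <- e - s
    if (len < minLen || len > maxLen) next
    pep <- substr(protein, i, j)
    if (grepl("X", pep, fixed = TRUE)) next
    out <- c(out, pep)
  }
  sort(out)
}

# O(n^2) single-pass greedy clustering oracle under the stated
# ordering (length desc, ties lexicographic)
oracleCluster <- function(peptides, threshold) {
  sorted <- peptides[order(-nchar(peptides), peptides)]
  reps <- character(); assign <- integer(length(sorted))
  for (i in seq_along(sorted)) {
    found <- 0L
    for (k in seq_along(reps)) {
      if (pairwiseIdentity(reps[k], sorted[i]) >= threshold) {
        found <- k; break
      }
    }
    if (found == 0L) { reps <- c(reps, sorted[i]); found <- length(reps) }
    assign[i] <- found
  }
  list(representatives = reps, member = sorted, cluster = assign)
}

# exact Shapley oracle by direct subset enumeration (no bit tricks)
oracleShapley <- function(fn, peptide, enc) {
  L <- nchar(peptide)
  x <- as.vector(encodePeptides(peptide, enc))
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), L))
  evalS <- function(mask) {
    row <- integer(enc@maxLen)
    row[seq_len(L)][mask] <- x[seq_len(L)][mask]
    fn(matrix(row, 1L))
  }
  fvals <- apply(subsets, 1L, function(m) evalS(as.logical(m)))
  vals <- numeric(L)
  for (i in seq_len(L)) {
    for (r in seq_len(nrow(subsets))) {
      m <- as.logical(subsets[r, ])
      if (m[i]) next
      s <- sum(m)
      w <- factorial(s) * factorial(L - 1 - s) / factorial(L)
      m1 <- m; m1[i] <- TRUE
      r1 <- which(apply(subsets, 1L, function(q)
        all(as.logical(q) == m1)))
      vals[i] <- vals[i] + w * (fvals[r1] - fvals[r])
    }
  }
  vals
}

# random peptide strings
randomPeptides <- function(n, lenRange = c(4, 12)) {
  vapply(seq_len(n), function(i) {
    L <- sample(lenRange[1]:lenRange[2], 1)
    paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = "")
  }, character(1))
}

# small trained sub-models shared across test files (trained once);
# quality is irrelevant -- only the probability contract matters here
.tinyModelCache <- new.env(parent = emptyenv())
tinyModels <- function() {
  if (is.null(.tinyModelCache$models)) {
    corpus <- syntheticCorpus(40, lenRange = c(5L, 10L), seed = 202)
    enc <- encodingSpec(10)
    .tinyModelCache$models <- lapply(
      c(cnn = "cnn", lstm = "lstm", attention = "attention",
        transformer = "transformer"),
      function(k) trainSubModel(
        corpus$sequence, corpus$label,
        subModelConfig(k, embeddingDim = 8L, filters = 8L,
                       hidden = 8L, attnDim = 8L, heads = 2L,
                       blocks = 1L, ffnDim = 12L, epochs = 4L,
                       seed = 303L),
        enc, quiet = TRUE))
  }
  .tinyModelCache$models
}

tinyEnsemble <- function() umamiEnsemble(unname(tinyModels()))
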