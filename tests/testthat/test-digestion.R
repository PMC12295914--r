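bothEnzymes <- list(enzymePreset("trypsin"), enzymePreset("chymotrypsin-high"))

test_that("cleavage sites follow the after-residue rule with proline block", {
  expect_equal(cleavageSites("AAAA", enzymePreset("trypsin")), integer())
  expect_equal(cleavageSites("MKAYR", bothEnzymes), c(2L, 4L))
  expect_equal(cleavageSites("AKPA", enzymePreset("trypsin")), integer())
  expect_equal(cleavageSites("AKAPA", enzymePreset("trypsin")), 2L)
  expect_error(cleavageSites("", bothEnzymes), "empty")
})

test_that("digestion emits fragments, missed-cleavage windows and filters", {
  p <- digestParams(rules = bothEnzymes, minLenAa = 1, maxLenAa = 10)
  expect_equal(digestProtein("MKAYR", p)$sequence, c("MK", "AY", "R"))

  p1 <- digestParams(rules = bothEnzymes, maxMissedCleavages = 1,
                     minLenAa = 1, maxLenAa = 10)
  d1 <- digestProtein("MKAYR", p1)
  expect_setequal(d1$sequence, c("MK", "AY", "R", "MKAY", "AYR"))
  expect_equal(d1$missed_cleavages[d1$sequence == "MKAY"], 1L)

  # no cut sites: identity if within bounds
  expect_equal(digestProtein("AAAA", p)$sequence, "AAAA")
  # X-containing peptides are dropped
  expect_equal(nrow(digestProtein("AXAA", p)), 0L)
  # coordinates slice the parent
  d <- digestProtein("MKAYR", p1)
  expect_true(all(substring("MKAYR", d$start_aa + 1, d$end_aa) ==
                    d$sequence))
})

test_that("unfiltered fragments tile the protein and obey the count law", {
  set.seed(81)
  for (rep in 1:30) {
    prot <- paste(sample(AA_ALPHABET20, sample(10:60, 1),
                         replace = TRUE), collapse = "")
    p0 <- digestParams(rules = bothEnzymes, minLenAa = 1,
                       maxLenAa = nchar(prot))
    frags <- digestProtein(prot, p0)
    expect_equal(paste(frags$sequence, collapse = ""), prot)
    ncuts <- length(cleavageSites(prot, bothEnzymes))
    expect_equal(nrow(frags), ncuts + 1L)
  }
})

test_that("digestion equals the brute-force window oracle on random proteins", {
  set.seed(82)
  for (rep in 1:100) {
    prot <- paste(sample(c(AA_ALPHABET20, "X"),
                         sample(8:40, 1), replace = TRUE,
                         prob = c(rep(1, 20), 0.6)), collapse = "")
    m <- sample(0:3, 1)
    minL <- sample(1:3, 1); maxL <- sample(6:20, 1)
    p <- digestParams(rules = bothEnzymes, maxMissedCleavages = m,
                      minLenAa = minL, maxLenAa = maxL)
    mine <- sort(digestProtein(prot, p)$sequence)
    expect_equal(mine, oracleDigest(prot, bothEnzymes, m, minL, maxL))
  }
})

test_that("peptide count never decreases with more missed cleavages", {
  set.seed(83)
  for (rep in 1:20) {
    prot <- paste(sample(AA_ALPHABET20, 40, replace = TRUE),
                  collapse = "")
    counts <- vapply(0:4, function(m)
      nrow(digestProtein(prot, digestParams(
        rules = bothEnzymes, maxMissedCleavages = m,
        minLenAa = 1, maxLenAa = 40))), integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("multi-protein digestion preserves parent identifiers", {
  out <- digestProteins(c(a = "MKAYR", b = "AAAA"),
                        digestParams(rules = bothEnzymes,
                                     minLenAa = 1, maxLenAa = 10))
  expect_setequal(unique(out$parent_id), c("a", "b"))
  expect_equal(out$sequence[out$parent_id == "b"], "AAAA")
})
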