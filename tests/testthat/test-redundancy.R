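test_that("pairwise identity follows the shorter-sequence convention", {
  expect_equal(pairwiseIdentity("PEPTIDE", "PEPTIDE"), 1.0)
  expect_equal(pairwiseIdentity("AAAAAAAAAV", "AAAAAAAAAA"), 0.9)
  expect_equal(pairwiseIdentity("KKKK", "DDDD"), 0.0)
  # shorter-sequence denominator: a perfect substring scores 1
  expect_equal(pairwiseIdentity("PEPTIDE", "PEP"), 1.0)
  expect_error(pairwiseIdentity("", "A"), "empty")
})

test_that("identity is symmetric, bounded, and score-consistent with an alignment oracle", {
  mat <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  diag(mat) <- 1
  set.seed(91)
  for (rep in 1:60) {
    a <- paste(sample(AA_ALPHABET20, sample(3:12, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(AA_ALPHABET20, sample(3:12, 1), replace = TRUE),
               collapse = "")
    idAB <- pairwiseIdentity(a, b)
    expect_equal(idAB, pairwiseIdentity(b, a))
    expect_gte(idAB, 0); expect_lte(idAB, 1)
    # the DP score (matches - gap cost) must equal Needleman-Wunsch
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 1)
    myScore <- local({
      x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
      n <- length(x); m <- length(y)
      S <- matrix(0, n + 1, m + 1); S[, 1] <- -(0:n); S[1, ] <- -(0:m)
      for (i in seq_len(n)) for (j in seq_len(m))
        S[i + 1, j + 1] <- max(S[i, j] + (x[i] == y[j]),
                               S[i, j + 1] - 1, S[i + 1, j] - 1)
      S[n + 1, m + 1]
    })
    expect_equal(myScore, Biostrings::score(al))
  }
})

test_that("greedy clustering matches its spec examples", {
  expect_length(clusterPeptides(c("AAA", "AAA"), 0.9)$representatives, 1L)
  cl <- clusterPeptides(c("AAAAAAAAAA", "AAAAAAAAAV", "WWWWWWWWWW"), 0.9)
  expect_length(cl$representatives, 2L)
  # threshold 1 on distinct sequences: every peptide its own cluster
  distinct <- c("AAAA", "CCCC", "DDDD", "EEEE")
  expect_length(clusterPeptides(distinct, 1.0)$representatives, 4L)
})

test_that("every member meets the threshold against its representative", {
  set.seed(92)
  peps <- randomPeptides(80, c(4, 10))
  cl <- clusterPeptides(peps, 0.8)
  ok <- mapply(function(m, r) m == r || pairwiseIdentity(r, m) >= 0.8,
               cl$clusters$member, cl$clusters$representative)
  expect_true(all(ok))
  # representatives are never shorter than members
  expect_true(all(nchar(cl$clusters$representative) >=
                    nchar(cl$clusters$member)))
})

test_that("re-clustering representatives below threshold is idempotent", {
  set.seed(93)
  peps <- randomPeptides(60, c(5, 10))
  cl <- clusterPeptides(peps, 0.9)
  reps <- cl$representatives
  pairsBelow <- TRUE
  for (i in seq_along(reps)) for (j in seq_len(i - 1))
    if (pairwiseIdentity(reps[i], reps[j]) >= 0.9) pairsBelow <- FALSE
  if (pairsBelow) {
    cl2 <- clusterPeptides(reps, 0.9)
    expect_equal(sort(cl2$representatives), sort(reps))
    expect_length(cl2$representatives, length(reps))
  } else succeed("greedy assignment made reps cross-threshold")
})

test_that("clustering equals the O(n^2) greedy oracle", {
  set.seed(94)
  peps <- c(randomPeptides(120, c(4, 12)),
            randomPeptides(40, c(4, 6)))   # short ones collide more
  for (thr in c(0.7, 0.9)) {
    mine <- clusterPeptides(peps, thr)
    orc <- oracleCluster(peps, thr)
    expect_equal(mine$representatives, orc$representatives)
    expect_equal(mine$clusters$member, orc$member)
    expect_equal(mine$clusters$cluster, orc$cluster)
  }
})
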