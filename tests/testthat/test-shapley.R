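enc6 <- encodingSpec(6)
idxD <- match("D", AA_ALPHABET20)    # 3

test_that("a constant model gives zero attributions (dummy axiom)", {
  f <- function(X) rep(0.37, nrow(X))
  at <- shapleyPositions(f, "MKLV", mode = "exact", encoding = enc6)
  expect_equal(unname(at@values), rep(0, 4))
  expect_equal(at@baseValue, 0.37)
  expect_equal(at@prediction, 0.37)
})

test_that("a single-position detector attributes everything to that position", {
  f <- function(X) as.numeric(X[, 1] == idxD)
  at <- shapleyPositions(f, "DAA", mode = "exact", encoding = enc6)
  expect_equal(unname(at@values), c(1, 0, 0))
  expect_equal(names(at@values), c("Pos_0", "Pos_1", "Pos_2"))
  expect_equal(at@baseValue, 0)
  expect_equal(at@prediction, 1)
})

test_that("symmetric players with equal residues get equal values", {
  f <- function(X) 0.1 * (X[, 2] == idxD) + 0.1 * (X[, 3] == idxD) +
    0.05 * (X[, 2] == idxD) * (X[, 3] == idxD)
  at <- shapleyPositions(f, "ADDA", mode = "exact", encoding = enc6)
  expect_equal(at@values[["Pos_1"]], at@values[["Pos_2"]])
})

test_that("exact values match direct subset enumeration on random models", {
  set.seed(41)
  for (rep in 1:5) {
    W <- matrix(rnorm(6 * 21, sd = 0.4), 6, 21)
    f <- function(X) {
      z <- vapply(seq_len(nrow(X)), function(i)
        sum(W[cbind(seq_len(ncol(X)), X[i, ] + 1L)]), numeric(1))
      1 / (1 + exp(-z))
    }
    pep <- paste(sample(AA_ALPHABET20, 5, replace = TRUE),
                 collapse = "")
    at <- shapleyPositions(f, pep, mode = "exact", encoding = enc6)
    expect_equal(unname(at@values), oracleShapley(f, pep, enc6),
                 tolerance = 1e-10)
    # efficiency axiom
    expect_equal(at@baseValue + sum(at@values), at@prediction,
                 tolerance = 1e-10)
  }
})

test_that("exact efficiency holds for trained sub-models and the ensemble", {
  models <- tinyModels()
  set.seed(42)
  peps <- randomPeptides(3, c(5, 9))
  for (m in models) for (pep in peps) {
    at <- shapleyPositions(m, pep, mode = "exact")
    expect_equal(at@baseValue + sum(at@values), at@prediction,
                 tolerance = 1e-6)
  }
  at <- shapleyPositions(tinyEnsemble(), peps[1], mode = "exact")
  expect_equal(at@baseValue + sum(at@values), at@prediction,
               tolerance = 1e-6)
})

test_that("sampled mode is efficient and converges to exact values", {
  set.seed(43)
  W <- matrix(rnorm(6 * 21, sd = 0.5), 6, 21)
  f <- function(X) {
    z <- vapply(seq_len(nrow(X)), function(i)
      sum(W[cbind(seq_len(ncol(X)), X[i, ] + 1L)]) +
        0.3 * (X[i, 1] == idxD) * (X[i, 2] == idxD), numeric(1))
    1 / (1 + exp(-z))
  }
  pep <- "DDAKLV"
  exact <- shapleyPositions(f, pep, mode = "exact", encoding = enc6)
  errAt <- function(n) {
    s <- shapleyPositions(f, pep, mode = "sampled", nSamples = n,
                          seed = 99, encoding = enc6)
    # antithetic permutation pairs keep the estimate exactly efficient
    expect_equal(s@baseValue + sum(s@values), s@prediction,
                 tolerance = 1e-10)
    mean(abs(s@values - exact@values))
  }
  errs <- vapply(c(50L, 500L, 5000L), errAt, numeric(1))
  expect_true(errs[2] < errs[1])
  expect_true(errs[3] < errs[2])
  expect_lt(errs[3], 0.01)
  expect_error(shapleyPositions(f, pep, mode = "sampled", nSamples = 5,
                                encoding = enc6), "nSamples >= 10")
})

test_that("exact mode refuses peptides beyond 15 positions", {
  f <- function(X) rep(0.5, nrow(X))
  long <- paste(rep("A", 16), collapse = "")
  expect_error(shapleyPositions(f, long, mode = "exact",
                                encoding = encodingSpec(20)),
               "L <= 15")
})

test_that("waterfall ordering and cumulation reach the prediction", {
  f <- function(X) 0.2 * (X[, 1] == idxD) - 0.1 * (X[, 2] == idxD) + 0.5
  at <- shapleyPositions(f, "DDA", mode = "exact", encoding = enc6)
  wf <- waterfallData(at)
  expect_equal(wf$value, unname(at@values[order(-abs(at@values))]))
  expect_equal(wf$cumulative[nrow(wf)], at@prediction, tolerance = 1e-10)
  expect_equal(wf$cumulative, at@baseValue + cumsum(wf$value))
  # one-residue peptide: a single bar
  at1 <- shapleyPositions(f, "D", mode = "exact", encoding = enc6)
  expect_equal(nrow(waterfallData(at1)), 1L)
})

test_that("global importance averages |values| and ranks planted positions", {
  f <- function(X) 0.4 * (X[, 1] == idxD) + 0.3 * (X[, 2] == idxD) + 0.1
  set.seed(44)
  peps <- c("DDKLV", "DAAG", "ADDL", "KLVA")
  gi <- globalImportance(f, peps, mode = "exact", encoding = enc6)
  expect_equal(gi$feature[1:2], c("Pos_0", "Pos_1"))
  expect_true(all(diff(gi$importance) <= 0))
  # single peptide: importance equals |values|
  at <- shapleyPositions(f, "DDKLV", mode = "exact", encoding = enc6)
  gi1 <- globalImportance(f, "DDKLV", mode = "exact", encoding = enc6)
  expect_equal(sort(gi1$importance), sort(unname(abs(at@values))))
  # constant model: all zero
  gi0 <- globalImportance(function(X) rep(0.2, nrow(X)), peps,
                          mode = "exact", encoding = enc6)
  expect_true(all(gi0$importance == 0))
  expect_error(globalImportance(f, character(), encoding = enc6),
               "empty")
})
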