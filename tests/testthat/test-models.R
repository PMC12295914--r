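test_that("encoding is left-aligned, padded and invertible", {
  spec <- encodingSpec(4)
  expect_equal(unname(encodePeptides("A", spec)[1, ]), c(1L, 0L, 0L, 0L))
  set.seed(11)
  peps <- randomPeptides(40, c(1, 4))
  X <- encodePeptides(peps, spec)
  expect_equal(unname(decodePeptides(X, spec)), peps)
  expect_error(encodePeptides(paste(rep("A", 5), collapse = ""), spec),
               "longer than maxLen")
  expect_warning(
    X2 <- encodePeptides(paste(rep("C", 6), collapse = ""), spec,
                         truncate = TRUE), "truncating")
  expect_equal(unname(X2[1, ]), rep(2L, 4))
})

gradCheckKind <- function(kind, ...) {
  set.seed(404)
  cfg <- subModelConfig(kind, ..., dropout = 0)
  X <- matrix(sample(0:20, 4 * 8, replace = TRUE), 4, 8)
  X[, 1] <- sample(1:20, 4)
  y <- c(1, 0, 1, 0)
  params <- UmamiForge:::.modelInit(cfg)
  fw <- UmamiForge:::.modelForward(kind, params, X, cfg)
  gr <- UmamiForge:::.modelBackward(kind, params, fw$cache,
                                    (fw$p - y) / 4)
  loss <- function(pp)
    UmamiForge:::.bceLoss(UmamiForge:::.modelForward(kind, pp, X, cfg)$p, y)
  worst <- 0
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (ii in idx) {
      p1 <- params; p1[[nm]][ii] <- p1[[nm]][ii] + 1e-6
      p2 <- params; p2[[nm]][ii] <- p2[[nm]][ii] - 1e-6
      fd <- (loss(p1) - loss(p2)) / 2e-6
      an <- gr[[nm]][ii]
      # absolute scale guard: a zero gradient (e.g. attention key
      # bias, which cancels in softmax) is compared absolutely
      err <- abs(fd - an) / max(1e-6, abs(fd) + abs(an))
      worst <- max(worst, err)
    }
  }
  worst
}

test_that("analytic gradients match finite differences for all four models", {
  expect_lt(gradCheckKind("cnn", embeddingDim = 6, filters = 5), 1e-4)
  expect_lt(gradCheckKind("lstm", embeddingDim = 6, hidden = 5), 1e-4)
  expect_lt(gradCheckKind("attention", embeddingDim = 6, attnDim = 5),
            1e-4)
  expect_lt(gradCheckKind("transformer", embeddingDim = 8, heads = 2,
                          blocks = 2, ffnDim = 10), 1e-4)
})

test_that("trained models satisfy the probability contract deterministically", {
  models <- tinyModels()
  peps <- randomPeptides(10, c(4, 10))
  for (m in models) {
    p1 <- predict(m, peps)
    expect_true(all(p1 >= 0 & p1 <= 1))
    expect_identical(p1, predict(m, peps))   # inference determinism
  }
})

test_that("saved model artifacts round-trip with identical predictions", {
  m <- tinyModels()$cnn
  path <- withr::local_tempfile(fileext = ".rds")
  saveSubModel(m, path)
  m2 <- loadSubModel(path)
  peps <- randomPeptides(5, c(4, 9))
  expect_identical(predict(m, peps), predict(m2, peps))
  expect_equal(m2@config$seed, m@config$seed)
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), other)
  expect_error(loadSubModel(other), "UmamiSubModel")
})

test_that("split manifests record the full partition as JSON", {
  corpus <- syntheticCorpus(20, seed = 3)
  sp <- splitCorpus(corpus, 0.8, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  writeSplitManifest(sp, path, seed = 4, trainFraction = 0.8)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(man$n_train, nrow(sp$train))
  expect_equal(sort(c(man$train$sequence, man$test$sequence)),
               sort(corpus$sequence))
})

test_that("same seed reproduces training; constant labels are flagged", {
  corpus <- syntheticCorpus(15, lenRange = c(5L, 8L), seed = 7)
  cfg <- subModelConfig("cnn", embeddingDim = 8, filters = 8,
                        epochs = 3, seed = 99)
  m1 <- trainSubModel(corpus$sequence, corpus$label, cfg,
                      encodingSpec(8), quiet = TRUE)
  m2 <- trainSubModel(corpus$sequence, corpus$label, cfg,
                      encodingSpec(8), quiet = TRUE)
  expect_identical(m1@params, m2@params)

  expect_message(
    trainSubModel(corpus$sequence[corpus$label == 1],
                  rep(1, sum(corpus$label == 1)), cfg, encodingSpec(8)),
    "constant-label")
})
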