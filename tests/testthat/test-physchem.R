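# Golden panel: the ten candidate peptides with their published
# molecular weight (Da), theoretical pI, GRAVY and net charge at pH 7
goldenPanel <- data.frame(
  sequence = c("DDSMAATGL", "ADEETGA", "DGEEDASM", "EEDEAK",
               "DSDVAVAVV", "DTAVSTVAQ", "EEVDEAR", "ESEGESGK",
               "EEEEKK", "DEEEVDI"),
  mw = c(879.94, 691.65, 852.82, 719.7, 873.96, 890.95, 846.85,
         821.80, 790.83, 847.83),
  pI = c(3.56, 3.57, 3.43, 4.00, 3.56, 3.80, 4.00, 4.25, 4.49, 3.39),
  gravy = c(0.044, -1.143, -1.438, -2.683, 1.4, 0.311, -1.786, -2.1,
            -3.633, -1.257),
  charge = c(-2.1, -3.1, -4.1, -3.1, -2.1, -1.1, -3.1, -2.1, -2.1,
             -5.1))

test_that("GRAVY matches the published panel to 3 decimals", {
  for (i in seq_len(nrow(goldenPanel)))
    expect_equal(round(gravy(goldenPanel$sequence[i]), 3),
                 goldenPanel$gravy[i])
  expect_equal(gravy("GGGG"), -0.4)
  expect_error(gravy(""), "empty")
})

test_that("molecular weight matches the published panel within 0.1 Da", {
  expect_equal(molecularWeight("G"), 75.07, tolerance = 0.01)
  for (i in seq_len(nrow(goldenPanel)))
    expect_lt(abs(molecularWeight(goldenPanel$sequence[i]) -
                    goldenPanel$mw[i]), 0.1)
})

test_that("molecular weight is additive up to one condensation water", {
  set.seed(51)
  for (i in 1:20) {
    a <- randomPeptides(1, c(2, 8)); b <- randomPeptides(1, c(2, 8))
    expect_equal(molecularWeight(paste0(a, b)),
                 molecularWeight(a) + molecularWeight(b) - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("GRAVY is invariant under residue shuffling", {
  set.seed(52)
  for (i in 1:20) {
    p <- randomPeptides(1, c(5, 12))
    sh <- paste(sample(strsplit(p, "")[[1]]), collapse = "")
    expect_equal(gravy(p), gravy(sh))
  }
})

test_that("net charge at pH 7 matches the published panel within 0.05 e", {
  for (i in seq_len(nrow(goldenPanel)))
    expect_lt(abs(netCharge(goldenPanel$sequence[i]) -
                    goldenPanel$charge[i]), 0.05)
})

test_that("net charge decreases strictly with pH", {
  set.seed(53)
  for (i in 1:10) {
    p <- randomPeptides(1, c(4, 10))
    phs <- seq(1, 13, by = 1.5)
    ch <- vapply(phs, function(x) netCharge(p, x), numeric(1))
    expect_true(all(diff(ch) < 0))
  }
})

test_that("pI matches the published panel within 0.05 and zeroes the charge", {
  for (i in seq_len(nrow(goldenPanel))) {
    pI <- isoelectricPoint(goldenPanel$sequence[i])
    expect_lt(abs(pI - goldenPanel$pI[i]), 0.05)
    expect_lt(abs(netCharge(goldenPanel$sequence[i], pI,
                            pkaSet("protparam"))), 1e-4)
  }
  expect_gt(isoelectricPoint("KKKKK"), isoelectricPoint("DDDDD"))
})

test_that("profile table carries all panel columns plus the toxicity hook", {
  prof <- physChemProfile(c("DDSMAATGL", "EEEEKK"))
  expect_equal(names(prof), c("sequence", "mw", "pI", "gravy",
                              "charge", "toxicity"))
  expect_true(all(is.na(prof$toxicity)))
  expect_equal(round(prof$gravy[1], 3), 0.044)
})
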