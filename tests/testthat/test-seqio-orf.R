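test_that("FASTA reading handles wrapping, case, and validation", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a first", "acg", "t", ">b", "TTTT"), fa)
  recs <- readNucleotideFasta(fa)
  expect_length(recs, 2L)
  expect_equal(as.character(recs), c(a = "ACGT", b = "TTTT"))
  expect_equal(S4Vectors::mcols(recs)$description[1], "a first")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGQ"), bad)
  expect_error(readNucleotideFasta(bad), "'Q' at position 4")
  expect_error(readNucleotideFasta(file.path(tempdir(), "nope.fa")),
               "not found")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "", ">b", "ACGT"), empty)
  expect_error(readNucleotideFasta(empty), "empty sequence")
})

test_that("simple ORFs are found with correct translation and coordinates", {
  orfs <- findOrfs("ATGAAATAA", minLenNt = 6)
  fwd <- orfs[S4Vectors::mcols(orfs)$frame == 1L]
  expect_equal(as.character(fwd), "MK", ignore_attr = TRUE)
  expect_equal(S4Vectors::mcols(fwd)$start_nt, 0L)
  expect_equal(S4Vectors::mcols(fwd)$end_nt, 6L)

  # no stop codon: the maximal run spans the whole frame
  orfs2 <- findOrfs("TTTTTT", minLenNt = 6)
  f1 <- orfs2[S4Vectors::mcols(orfs2)$frame == 1L]
  expect_equal(as.character(f1), "FF", ignore_attr = TRUE)

  expect_error(findOrfs("ATGAAATAA", minLenNt = 7), "multiple of 3")
})

test_that("codons containing N translate to X", {
  orfs <- findOrfs("ATGANATAA", minLenNt = 6)
  f1 <- as.character(orfs[S4Vectors::mcols(orfs)$frame == 1L])
  expect_equal(unname(f1), "MX")
})

test_that("reverse-complement symmetry and coordinate round-trip hold", {
  set.seed(71)
  for (rep in 1:25) {
    seqStr <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                    collapse = "")
    dna <- Biostrings::DNAStringSet(setNames(seqStr, "x"))
    rc <- Biostrings::reverseComplement(dna)
    names(rc) <- "x"
    o1 <- findOrfs(dna, minLenNt = 9)
    o2 <- findOrfs(rc, minLenNt = 9)
    expect_equal(sort(as.character(o1)), sort(as.character(o2)))
    m1 <- table(S4Vectors::mcols(o1)$frame)
    m2 <- table(-S4Vectors::mcols(o2)$frame)
    expect_equal(m1[order(names(m1))], m2[order(names(m2))])
    # coordinates round-trip through re-translation
    mc <- S4Vectors::mcols(o1)
    for (i in seq_along(o1)) {
      expect_equal(translateRegion(seqStr, mc$start_nt[i], mc$end_nt[i],
                                   mc$frame[i]),
                   as.character(o1[[i]]))
    }
  }
})

test_that("ORF extraction matches an independent whole-frame translation oracle", {
  set.seed(72)
  for (rep in 1:100) {
    seqStr <- paste(sample(c("A", "C", "G", "T"),
                           sample(30:150, 1), replace = TRUE),
                    collapse = "")
    minLen <- sample(c(9L, 15L, 30L), 1)
    mine <- findOrfs(seqStr, minLenNt = minLen)
    orc <- oracleOrfs(seqStr, minLen)
    expect_equal(sort(as.character(mine)),
                 sort(vapply(orc, `[[`, character(1), "protein")))
    expect_false(any(grepl("*", as.character(mine), fixed = TRUE)))
  }
})

test_that("protein FASTA headers carry parent, frame and coordinates", {
  orfs <- findOrfs(Biostrings::DNAStringSet(c(ctg = "ATGAAATAA")),
                   minLenNt = 6)
  out <- withr::local_tempfile(fileext = ".faa")
  writeProteinFasta(orfs, out)
  headers <- grep("^>", readLines(out), value = TRUE)
  expect_true(">ctg|+1|0-6" %in% headers)
})
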