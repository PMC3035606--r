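test_that("msaProfile validates shape and maps reference numbering", {
  seqs <- c(ref = "AC-DE", other = "ACWDE", third = "AC-DF")
  p <- msaProfile(seqs, "ref")
  expect_s4_class(p, "MsaProfile")
  expect_equal(p@referenceMap, c(1L, 2L, NA, 3L, 4L))
  expect_error(msaProfile(c(a = "ACD", b = "AC"), "a"), "ragged")
  expect_error(msaProfile(seqs, "nope"), "nope")
  expect_error(msaProfile(seqs["ref"], "ref"), "at least 2")
})

test_that("readMsa round-trips a generated aligned FASTA", {
  fx <- makeMsaFixture(nSeqs = 5, length = 30, conservedColumns = c(3, 9),
                       seed = 7)
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(fx$text, f)
  p <- readMsa(f, "seq01")
  expect_identical(p@aln, fx$profile@aln)
  expect_identical(p@ids, fx$profile@ids)
})

test_that("columnConservation scores modal training frequency, gaps excluded", {
  seqs <- c(A = "QQQQ", B = "QQQA", C = "QQAA", D = "QQ--")
  p <- msaProfile(seqs, "A")
  sc <- columnConservation(p, c("A", "B", "C", "D"))
  expect_equal(sc$score, c(1, 1, 2 / 4, 2 / 4))
  allGap <- msaProfile(c(A = "Q-", B = "Q-", C = "Q-"), "A")
  expect_equal(columnConservation(allGap, c("A", "B", "C"))$score[2], 0)
  expect_error(columnConservation(p, character(0)), "empty training set")
  expect_error(columnConservation(p, c("A", "Z")), "Z")
})

test_that("planted conserved columns are recovered exactly at full mutation", {
  planted <- c(4, 9, 15, 22)
  fx <- makeMsaFixture(nSeqs = 6, length = 30, conservedColumns = planted,
                       mutationRate = 1, seed = 19)
  sc <- columnConservation(fx$profile, fx$profile@ids)
  found <- conservedInterfacePositions(sc, interfacePositions = 1:30,
                                       threshold = 1,
                                       trainingIds = fx$profile@ids)
  expect_equal(found@positions, planted)
  expect_true(all(found@scores == 1))
})

test_that("conserved-position sets shrink monotonically with the threshold", {
  fx <- makeMsaFixture(nSeqs = 6, length = 40, conservedColumns = c(2, 8, 30),
                       mutationRate = 0.4, seed = 3)
  sc <- columnConservation(fx$profile, fx$profile@ids)
  prev <- NULL
  for (th in c(0.3, 0.5, 5 / 6, 1)) {
    cur <- conservedInterfacePositions(sc, 1:40, threshold = th)@positions
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("conserved positions intersect the structural interface", {
  fx <- makeMsaFixture(nSeqs = 6, length = 10, conservedColumns = 1:10,
                       seed = 5)
  sc <- columnConservation(fx$profile, fx$profile@ids)
  cps <- conservedInterfacePositions(sc, interfacePositions = c(2, 5, 6),
                                     threshold = 1)
  expect_equal(cps@positions, c(2L, 5L, 6L))
  # an InterfaceReport can stand in for the position vector
  cf <- makeContactFixture()
  ir <- interfaceResidues(cf$model, chainGroup("A"), chainGroup("B"))
  cps2 <- conservedInterfacePositions(sc, ir, threshold = 1)
  expect_equal(cps2@positions, as.integer(cf$contactZone))
})

test_that("reference gap columns never become interface positions", {
  seqs <- c(ref = "AA-AA", s2 = "AAWAA", s3 = "AAWAA", s4 = "AAWAA")
  p <- msaProfile(seqs, "ref")
  sc <- columnConservation(p, c("s2", "s3", "s4"))
  cps <- conservedInterfacePositions(sc, 1:5, threshold = 1)
  expect_equal(cps@positions, 1:4)  # reference numbering, gap column dropped
})

test_that("substituteResidue edits one position through reference numbering", {
  seqs <- c(ref = "QW-ERTY", s2 = "QWAERTY", s3 = "QWAERTY")
  p <- msaProfile(seqs, "ref")
  q <- substituteResidue(p, "s2", 3, "L")  # reference position 3 = column 4
  expect_equal(unname(q@aln["s2", 4]), "L")
  expect_equal(q@aln["s2", -4], p@aln["s2", -4])
  expect_error(substituteResidue(p, "missing", 3, "L"), "missing")
})
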