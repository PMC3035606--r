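positionsFromRef <- function(profile, pos, trainingIds) {
  sc <- columnConservation(profile, trainingIds)
  keep <- sc$refPos %in% pos & !is.na(sc$refPos)
  scores <- rep(1, sum(keep)); names(scores) <- sc$refPos[keep]
  new("ConservedPositionSet", positions = as.integer(sc$refPos[keep]),
      scores = scores, threshold = 1, trainingIds = trainingIds)
}

test_that("scoreCandidate counts strict identity to any training residue", {
  seqs <- c(t1 = "QWERT", t2 = "QWART", cand = "QWAKT", gappy = "QW-R-")
  p <- msaProfile(seqs, "t1")
  pos <- positionsFromRef(p, 1:5, c("t1", "t2"))
  sc <- scoreCandidate("cand", p, pos, c("t1", "t2"))
  expect_s4_class(sc, "CandidateScore")
  expect_equal(sc@nTotal, 5L)
  expect_equal(sc@nMatch, 4L)  # position 4: K vs training R only
  expect_equal(sc@mismatches$position, 4L)
  expect_equal(sc@mismatches$candidate, "K")
  gap <- scoreCandidate("gappy", p, pos, c("t1", "t2"))
  expect_true(3L %in% gap@mismatches$position)  # gap counts as mismatch
  expect_true(5L %in% gap@mismatches$position)
})

test_that("scoring a training member warns about circularity", {
  seqs <- c(t1 = "QWERT", t2 = "QWART")
  p <- msaProfile(seqs, "t1")
  pos <- positionsFromRef(p, 1:5, c("t1", "t2"))
  expect_warning(sc <- scoreCandidate("t1", p, pos, c("t1", "t2")),
                 "training")
  expect_equal(sc@nMatch, 5L)  # self-identity
  expect_error(scoreCandidate("nope", p, pos, "t1"), "nope")
})

test_that("catalyticCheck requires Gln or Glu at the catalytic position", {
  seqs <- c(ref = "AAQAA", e = "AAEAA", h = "AAHAA", g = "AA-AA")
  p <- msaProfile(seqs, "ref")
  expect_true(catalyticCheck("ref", p, 3)$pass)
  expect_true(catalyticCheck("e", p, 3)$pass)
  chk <- catalyticCheck("h", p, 3)
  expect_false(chk$pass)
  expect_equal(chk$residue, "H")
  expect_false(catalyticCheck("g", p, 3)$pass)
})

test_that("side-chain construction honours its internal coordinates", {
  bb <- list(N = c(0, 0, 0), CA = c(1.46, 0, 0), C = c(2.0, 1.42, 0))
  side <- buildSideChain("LYS", bb, c(-60, 180, 180, 180))
  expect_setequal(names(side), c("CB", "CG", "CD", "CE", "NZ"))
  expect_equal(dihedralAngle(bb$N, bb$CA, side$CB, side$CG), -60,
               tolerance = 1e-6)
  expect_equal(dihedralAngle(bb$CA, side$CB, side$CG, side$CD), 180,
               tolerance = 1e-6)
  expect_equal(sqrt(sum((side$CB - side$CG)^2)), 1.53, tolerance = 0.02)
  expect_length(buildSideChain("GLY", bb, numeric(0)), 0)
  expect_error(buildSideChain("PRO", bb, 30), "unsupported")
  expect_error(buildSideChain("LYS", bb, c(-60, 180)), "chi")
})

test_that("rotamer library covers the standard mutatable residues", {
  lib <- defaultRotamerLibrary()
  expect_true(all(c("HIS", "LYS", "LEU", "GLY", "ALA") %in% names(lib)))
  expect_equal(nrow(lib$HIS), 8)
  expect_equal(nrow(lib$LYS), 12)
  expect_equal(nrow(lib$LEU), 4)
  expect_false("PRO" %in% supportedResidues())
})

test_that("mutateAndScan reports planted pocket obstruction fractions", {
  tight <- makePocketFixture(3, seed = 8)
  wide <- makePocketFixture(12, seed = 8)
  expect_equal(mutateAndScan(tight$model, tight$chain, tight$position,
                             "HIS")@clashFreeFraction, 0)
  expect_equal(mutateAndScan(wide$model, wide$chain, wide$position,
                             "HIS")@clashFreeFraction, 1)
  expect_equal(mutateAndScan(wide$model, wide$chain, wide$position,
                             "LYS")@clashFreeFraction, 1)
  # glycine has no side chain to clash, even in the tight pocket
  expect_equal(mutateAndScan(tight$model, tight$chain, tight$position,
                             "GLY")@clashFreeFraction, 1)
})

test_that("clash-free fraction is monotone in the overlap cutoff", {
  fx <- makePocketFixture(4.2, seed = 9)
  fr <- vapply(c(0.1, 0.4, 1.0, 10.0), function(cut)
    mutateAndScan(fx$model, fx$chain, fx$position, "HIS",
                  overlapCutoff = cut)@clashFreeFraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[4], 1)  # a huge tolerance accepts every rotamer
})

test_that("mutateAndScan validates its target residue", {
  fx <- makePocketFixture(12, seed = 1)
  expect_error(mutateAndScan(fx$model, fx$chain, 999, "HIS"), "not modeled")
  expect_error(mutateAndScan(fx$model, fx$chain, fx$position, "PRO"),
               "unsupported")
})

verdictInputs <- function() {
  seqs <- c(t1 = "QAAAA", t2 = "QAAAC", cand = "QAAAC")
  p <- msaProfile(seqs, "t1")
  pos <- positionsFromRef(p, 2:5, c("t1", "t2"))
  list(p = p, pos = pos,
       score = scoreCandidate("cand", p, pos, c("t1", "t2")),
       catalytic = catalyticCheck("cand", p, 1))
}

test_that("predictPhosphatase combines the three evidence axes", {
  v <- verdictInputs()
  expect_equal(predictPhosphatase(v$score, v$catalytic, list())@call,
               "phosphatase")
  badCat <- v$catalytic; badCat$pass <- FALSE; badCat$residue <- "H"
  expect_equal(predictPhosphatase(v$score, badCat, list())@call,
               "non-phosphatase")
  lowId <- v$score
  lowId@nMatch <- 1L
  lowId@mismatches <- data.frame(position = 2:4,
                                 candidate = c("X", "X", "X"),
                                 training = c("A", "A", "A/C"))
  expect_equal(predictPhosphatase(lowId, v$catalytic, list())@call,
               "non-phosphatase")
  blockedReport <- new("ClashReport", chainId = "A", position = 2L,
                       insert = "", newResidue = "TRP",
                       rotamerOverlaps = c(2, 3), clashFreeFraction = 0,
                       overlapCutoff = 0.4)
  vb <- predictPhosphatase(lowId2 <- {
    s <- v$score; s@nMatch <- 3L
    s@mismatches <- data.frame(position = 2L, candidate = "W",
                               training = "A")
    s
  }, v$catalytic, list(blockedReport), identityThreshold = 0.5)
  expect_equal(vb@call, "non-phosphatase")
  expect_equal(vb@blockedPositions, 2L)
})

test_that("verdicts without structural evidence stay indeterminate", {
  v <- verdictInputs()
  s <- v$score
  s@nMatch <- 3L
  s@mismatches <- data.frame(position = 2L, candidate = "W", training = "A")
  expect_equal(predictPhosphatase(s, v$catalytic, NULL,
                                  identityThreshold = 0.5)@call,
               "indeterminate")
  # with no mismatches there is nothing to scan: call is decisive
  expect_equal(predictPhosphatase(v$score, v$catalytic, NULL)@call,
               "phosphatase")
})

test_that("verdicts are deterministic and leave-one-out training calls pass", {
  fx <- makeMsaFixture(nSeqs = 6, length = 40, conservedColumns = 1:12,
                       mutationRate = 0.15, seed = 31)
  ids <- fx$profile@ids
  # force a catalytic Gln into a planted column for every sequence
  p <- fx$profile
  for (id in ids) p <- substituteResidue(p, id, 5, "Q")
  for (held in ids) {
    training <- setdiff(ids, held)
    sc <- columnConservation(p, training)
    pos <- conservedInterfacePositions(sc, 1:40, threshold = 1,
                                       trainingIds = training)
    score <- scoreCandidate(held, p, pos, training)
    verdict <- predictPhosphatase(score, catalyticCheck(held, p, 5), list())
    again <- predictPhosphatase(score, catalyticCheck(held, p, 5), list())
    expect_equal(verdict@call, "phosphatase")
    expect_identical(verdict, again)
  }
})
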