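test_that("dihedralAngle reproduces cis = 0 and trans = 180", {
  expect_equal(dihedralAngle(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0),
                             c(3, 1, 0)), 0)
  expect_equal(dihedralAngle(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0),
                             c(3, -1, 0)), 180)
  # right-handed sign convention
  expect_gt(dihedralAngle(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0),
                          c(3, 0.5, 0.5)), 0)
})

test_that("dihedralAngle agrees with an independent formulation", {
  set.seed(11)
  for (k in 1:1000) {
    q <- randomQuadruple()
    a1 <- dihedralAngle(q[[1]], q[[2]], q[[3]], q[[4]])
    a2 <- dihedralByProjection(q[[1]], q[[2]], q[[3]], q[[4]])
    expect_lt(angularDifference(a1, a2), 1e-9)
  }
})

test_that("dihedralAngle agrees with bio3d's torsion", {
  set.seed(12)
  for (k in 1:100) {
    q <- randomQuadruple()
    a1 <- dihedralAngle(q[[1]], q[[2]], q[[3]], q[[4]])
    a2 <- bio3d::torsion.xyz(unlist(q), atm.inc = 4)
    expect_lt(angularDifference(a1, as.numeric(a2)), 1e-6)
  }
})

test_that("dihedralAngle is invariant under rigid transforms", {
  set.seed(13)
  for (k in 1:50) {
    q <- randomQuadruple()
    a1 <- dihedralAngle(q[[1]], q[[2]], q[[3]], q[[4]])
    rt <- randomRigid()
    qt <- lapply(q, function(p) as.numeric(rt$R %*% p) + rt$t)
    a2 <- dihedralAngle(qt[[1]], qt[[2]], qt[[3]], qt[[4]])
    expect_lt(angularDifference(a1, a2), 1e-8)
  }
})

test_that("degenerate dihedral inputs are errors, not numbers", {
  p <- c(0, 0, 0)
  expect_error(dihedralAngle(p, p, c(1, 0, 0), c(2, 1, 0)), "coincident")
  expect_error(dihedralAngle(c(-1, 0, 0), p, c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("angularDifference wraps around the circle", {
  expect_equal(angularDifference(179, -179), 2)
  expect_equal(angularDifference(0, 180), 180)
  expect_equal(angularDifference(-45, 45), 90)
})

test_that("kabsch recovers applied rigid transforms to rmsd < 1e-6", {
  set.seed(21)
  for (k in 1:100) {
    n <- sample(4:20, 1)
    ref <- matrix(stats::rnorm(3 * n, sd = 5), ncol = 3)
    rt <- randomRigid()
    mob <- ref %*% t(rt$R)
    mob <- sweep(mob, 2, rt$t, "+")
    sup <- kabsch(mob, ref)
    expect_lt(sup@rmsd, 1e-6)
    aligned <- sweep(mob %*% t(sup@rotation), 2, sup@translation, "+")
    expect_lt(max(abs(aligned - ref)), 1e-6)
  }
})

test_that("kabsch rmsd is symmetric in its arguments", {
  set.seed(22)
  for (k in 1:20) {
    a <- matrix(stats::rnorm(30, sd = 4), ncol = 3)
    b <- a + matrix(stats::rnorm(30, sd = 0.5), ncol = 3)
    expect_equal(kabsch(a, b)@rmsd, kabsch(b, a)@rmsd, tolerance = 1e-9)
  }
})

test_that("kabsch beats a random-search oracle on small point sets", {
  set.seed(23)
  for (k in 1:5) {
    n <- sample(4:10, 1)
    ref <- matrix(stats::rnorm(3 * n, sd = 4), ncol = 3)
    mob <- ref + matrix(stats::rnorm(3 * n, sd = 1), ncol = 3)
    opt <- kabsch(mob, ref)@rmsd
    m0 <- sweep(mob, 2, colMeans(mob))
    r0 <- sweep(ref, 2, colMeans(ref))
    best <- Inf
    for (trial in 1:2000) {
      R <- randomRigid()$R
      best <- min(best, sqrt(sum((m0 %*% t(R) - r0)^2) / n))
    }
    expect_lte(opt, best + 1e-12)
  }
})

test_that("kabsch rejects collinear and undersized point sets", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(line, line + 1), "collinear")
  two <- matrix(stats::rnorm(6), ncol = 3)
  expect_error(kabsch(two, two), "at least 3")
})

test_that("superposeChains aligns two rigid copies of the same chain", {
  fx <- makeReceiverStateFixture("non-phosphorylated-like", seed = 5)
  set.seed(24)
  rt <- randomRigid()
  moved <- transformStructure(fx$model, rt$R, rt$t)
  map <- buildCorrespondence(moved, fx$model, "R", "R")
  expect_s4_class(map, "CorrespondenceMap")
  sup <- superposeChains(moved, fx$model, map)
  expect_equal(sup@nPairs, nrow(map@pairs))
  expect_lt(sup@rmsd, 1e-6)
})

test_that("buildCorrespondence needs at least three shared residues", {
  txt <- paste(vapply(1:2, function(i)
    pdbLine(serial = i, name = "CA", resName = "GLY", chain = "A",
            resSeq = i, x = i * 3.8, y = i^2, z = 0, element = "C"),
    character(1)), collapse = "\n")
  m <- parsePDBText(txt)
  expect_error(buildCorrespondence(m, m, "A", "A"), "fewer than 3")
})

test_that("pseudodihedralCa returns NA for a disordered window", {
  fx <- makeReceiverStateFixture("phosphorylated-like", seed = 2,
                                 loopAngle = 70)
  expect_equal(pseudodihedralCa(fx$model, fx$chain, 82), 70,
               tolerance = 1e-6)
  a <- atoms(fx$model)
  gone <- rapspec:::.structureFromAtoms(
    a[!(a$chainId == "R" & a$resSeq == 84 & a$name == "CA"), ])
  expect_true(is.na(pseudodihedralCa(gone, "R", 82)))
})
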