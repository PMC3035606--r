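test_that("fibonacciSphere is a deterministic unit-sphere lattice", {
  p <- fibonacciSphere(960)
  expect_equal(dim(p), c(960, 3))
  expect_equal(sqrt(rowSums(p^2)), rep(1, 960), tolerance = 1e-12)
  expect_identical(p, fibonacciSphere(960))  # no RNG involved
})

test_that("isolated-sphere SASA matches 4*pi*(r+probe)^2 within 0.5%", {
  for (r in c(1.4, 1.7, 2.0)) {
    fx <- makeTwoSphereFixture(r, r, 1000)
    s <- shrakeRupleySasa(fx$model, fx$radii)
    exact <- 4 * pi * (r + 1.4)^2
    for (area in s@atomArea)
      expect_lt(abs(area - exact) / exact, 0.005)
  }
})

test_that("SASA is exactly additive for non-interacting atoms", {
  fx <- makeTwoSphereFixture(1.7, 2.0, 1000)
  whole <- shrakeRupleySasa(fx$model, fx$radii)
  a <- shrakeRupleySasa(selectAtoms(fx$model, "A"), fx$radii)
  b <- shrakeRupleySasa(selectAtoms(fx$model, "B"), fx$radii)
  expect_identical(whole@total, a@total + b@total)
  bsa <- buriedSurfaceArea(fx$model, chainGroup("A"), chainGroup("B"),
                           radii = fx$radii)
  expect_identical(as.numeric(bsa), 0)
})

test_that("two-sphere buried area matches the spherical-cap formula to 1%", {
  cases <- list(c(1.7, 1.7, 3.0), c(1.7, 2.0, 4.0), c(1.4, 2.2, 3.5),
                c(2.0, 2.0, 5.5))
  for (cs in cases) {
    fx <- makeTwoSphereFixture(cs[1], cs[2], cs[3])
    exact <- fx$analytic(1.4)
    bsa <- as.numeric(buriedSurfaceArea(fx$model, chainGroup("A"),
                                        chainGroup("B"), radii = fx$radii))
    expect_lt(abs(bsa - exact$bsa) / exact$bsa, 0.01)
    s <- shrakeRupleySasa(fx$model, fx$radii)
    expect_lt(abs(s@total - exact$sasaComplex) / exact$sasaComplex, 0.01)
  }
})

test_that("SASA converges with the number of sphere points", {
  fx <- makeTwoSphereFixture(1.7, 2.0, 4.0)
  coarse <- shrakeRupleySasa(fx$model, fx$radii, nPoints = 960L)
  fine <- shrakeRupleySasa(fx$model, fx$radii, nPoints = 3840L)
  expect_lt(abs(coarse@total - fine@total) / fine@total, 0.02)
  expect_error(shrakeRupleySasa(fx$model, fx$radii, nPoints = 50L),
               "at least 100")
})

test_that("buried surface area is symmetric, non-negative and monotone", {
  seps <- c(6.0, 5.0, 4.0, 3.0)
  last <- -Inf
  for (d in seps) {
    fx <- makeTwoSphereFixture(1.7, 2.0, d)
    ab <- as.numeric(buriedSurfaceArea(fx$model, chainGroup("A"),
                                       chainGroup("B"), radii = fx$radii))
    ba <- as.numeric(buriedSurfaceArea(fx$model, chainGroup("B"),
                                       chainGroup("A"), radii = fx$radii))
    expect_equal(ab, ba, tolerance = 1e-9)
    expect_gte(ab, 0)
    expect_gte(ab, last)  # closer approach buries no less area
    last <- ab
  }
})

test_that("overlapping group definitions are rejected", {
  fx <- makeTwoSphereFixture(1.7, 2.0, 4.0)
  expect_error(buriedSurfaceArea(fx$model, chainGroup(c("A", "B")),
                                 chainGroup("B"), radii = fx$radii),
               "disjoint")
})

test_that("interfaceResidues recovers a planted contact zone on both sides", {
  fx <- makeContactFixture()
  ir <- interfaceResidues(fx$model, chainGroup("A"), chainGroup("B"))
  expect_s4_class(ir, "InterfaceReport")
  expect_equal(interfaceSide(ir, "A"), fx$contactZone)
  expect_equal(interfaceSide(ir, "B"), fx$contactZone)
  expect_equal(sum(ir@perResidue$dsasa), ir@totalBsa, tolerance = 1e-9)
  # an absurd threshold empties the interface without changing the total
  hi <- interfaceResidues(fx$model, chainGroup("A"), chainGroup("B"),
                          threshold = 1e6)
  expect_length(interfaceSide(hi, "A"), 0)
  expect_equal(hi@totalBsa, ir@totalBsa, tolerance = 1e-9)
})

test_that("default radius set distinguishes trigonal carbons", {
  rs <- defaultRadiusSet()
  at <- data.frame(resName = c("ALA", "ALA", "PHE", "LYS"),
                   name = c("CB", "C", "CG", "NZ"),
                   element = c("C", "C", "C", "N"),
                   stringsAsFactors = FALSE)
  r <- atomRadii(at, rs)
  expect_equal(r, c(1.87, 1.76, 1.76, 1.65))
  bad <- data.frame(resName = "UNK", name = "Q1", element = "Qq",
                    stringsAsFactors = FALSE)
  expect_error(atomRadii(bad, rs), "UNK.*Q1|Q1.*UNK")
})
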