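test_that("parsePDBText reads atoms, chains, altlocs and insertion codes", {
  model <- parsePDBText(smallPdbText())
  a <- atoms(model)
  expect_s4_class(model, "Structure")
  expect_setequal(chainIds(model), c("A", "B"))
  expect_equal(nAtoms(model), 9L)
  expect_equal(sum(a$altLoc != ""), 2L)
  ins <- a[a$resName == "GLY" & a$chainId == "A", ]
  expect_equal(ins$insert, "A")
  expect_true(any(a$isHetero & a$resName == "HOH"))
  ca <- a[a$serial == 2, ]
  expect_equal(c(ca$x, ca$y, ca$z), c(1.46, 0, 0))
  expect_equal(a$element[a$serial == 6], "H")
})

test_that("readPDB/writePDB round-trips coordinates and identity fields", {
  model <- resolveAltLocs(parsePDBText(smallPdbText()))
  f <- writeTempPdb(model)
  back <- readPDB(f)
  a1 <- atoms(model); a2 <- atoms(back)
  expect_equal(nrow(a1), nrow(a2))
  for (col in c("name", "resName", "chainId", "resSeq", "insert"))
    expect_equal(a2[[col]], a1[[col]], label = col)
  for (col in c("x", "y", "z"))
    expect_equal(a2[[col]], a1[[col]], tolerance = 1e-3, label = col)
})

test_that("resolveAltLocs keeps the highest occupancy and is idempotent", {
  model <- parsePDBText(smallPdbText())
  res <- resolveAltLocs(model)
  cb <- atoms(res)[atoms(res)$name == "CB", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$occupancy, 0.6)  # altloc B wins at 0.6 vs 0.4
  expect_equal(cb$altLoc, "")
  expect_true(res@resolvedAltLocs)
  expect_equal(atoms(resolveAltLocs(res)), atoms(res))
})

test_that("occupancy ties resolve to the alphabetically first altloc", {
  txt <- paste(c(
    pdbLine(serial = 1, name = "CB", altLoc = "B", resName = "ALA",
            chain = "A", resSeq = 1, x = 1, y = 0, z = 0, occ = 0.5,
            element = "C"),
    pdbLine(serial = 2, name = "CB", altLoc = "A", resName = "ALA",
            chain = "A", resSeq = 1, x = 2, y = 0, z = 0, occ = 0.5,
            element = "C")), collapse = "\n")
  res <- resolveAltLocs(parsePDBText(txt))
  expect_equal(atoms(res)$x, 2)
})

test_that("chainGroup parses chain and range specifications", {
  g <- chainGroup(c("A", "B:1-76"), "rec")
  expect_s4_class(g, "ChainGroup")
  expect_equal(g@chains, c("A", "B"))
  expect_null(g@ranges[[1]])
  expect_equal(g@ranges[[2]], 1:76)
  expect_error(chainGroup("B:9-2"), "range")
})

test_that("selectAtoms projects chains/ranges and errors on unknown chains", {
  model <- parsePDBText(smallPdbText())
  onlyA <- selectAtoms(model, "A")
  expect_setequal(chainIds(onlyA), "A")
  sub <- selectAtoms(model, chainGroup("A:1-1"))
  expect_true(all(atoms(sub)$resSeq == 1))
  again <- selectAtoms(onlyA, "A")
  expect_equal(atoms(again), atoms(onlyA))
  expect_error(selectAtoms(model, "Q"), "available chains.*A.*B")
})

test_that("heavy-atom selection drops hydrogens, waters and hetero atoms", {
  model <- parsePDBText(smallPdbText())
  heavy <- rapspec:::.proteinHeavyAtoms(model)
  expect_false(any(heavy$element %in% c("H", "D")))
  expect_false(any(heavy$resName %in% c("HOH", "WAT")))
  expect_false(any(heavy$isHetero))
})

test_that("malformed and empty PDB input produce informative errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdbLine(serial = 1, name = "CA", resName = "GLY", chain = "A",
                       resSeq = 1, x = 0, y = 0, z = 0, element = "C"),
               "ATOM      2  CA  GLY A   2        bad coordinates here"), f)
  expect_error(readPDB(f), "line 2")
  writeLines(c("HEADER    TEST", "END"), f)
  expect_error(readPDB(f), "empty|no ATOM")
  expect_error(readPDB(file.path(tempdir(), "does-not-exist.pdb")),
               "no such file")
})

test_that("atomDistance measures named atom pairs and names missing atoms", {
  model <- parsePDBText(smallPdbText())
  d <- atomDistance(model, "A", 1, "CA", "B", 1, "CA")
  expect_equal(d, 9.0 - 1.46, tolerance = 1e-6)
  expect_error(atomDistance(model, "A", 1, "XX", "B", 1, "CA"), "XX")
})
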