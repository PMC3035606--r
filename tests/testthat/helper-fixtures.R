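# Shared helpers for the rapspec test suite.

# Independent dihedral formulation (projection onto the plane normal to the
# central bond), used as an oracle against the atan2 implementation.
dihedralByProjection <- function(p1, p2, p3, p4) {
  b <- p3 - p2; b <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  v <- (p4 - p3) - sum((p4 - p3) * b) * b
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  ang <- acos(max(-1, min(1, sum(u * v)))) * 180 / pi
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sum(cr * b)
  if (s < 0) -ang else ang
}

# A random well-conditioned dihedral quadruple (no collinear triples).
randomQuadruple <- function() {
  repeat {
    pts <- lapply(1:4, function(i) stats::rnorm(3, sd = 3))
    ok <- TRUE
    for (k in 1:2) {
      u <- pts[[k + 1]] - pts[[k]]; v <- pts[[k + 2]] - pts[[k + 1]]
      n2 <- sum((c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
                   u[1] * v[2] - u[2] * v[1]))^2)
      if (n2 < 1e-4) ok <- FALSE
    }
    if (ok && sum((pts[[3]] - pts[[2]])^2) > 1e-2) return(pts)
  }
}

randomRigid <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  list(R = R, t = stats::runif(3, -20, 20))
}

# Minimal hand-written PDB text used by the parser tests (standard column
# layout, including altlocs, an insertion code, a hydrogen, and a water).
pdbLine <- function(record = "ATOM", serial, name, altLoc = " ", resName,
                    chain, resSeq, icode = " ", x, y, z, occ = 1, b = 10,
                    element) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altLoc, resName, chain, resSeq, icode,
          x, y, z, occ, b, element)
}

smallPdbText <- function() {
  paste(c(
    pdbLine(serial = 1, name = "N",  resName = "ALA", chain = "A", resSeq = 1,
            x = 0, y = 0, z = 0, element = "N"),
    pdbLine(serial = 2, name = "CA", resName = "ALA", chain = "A", resSeq = 1,
            x = 1.46, y = 0, z = 0, element = "C"),
    pdbLine(serial = 3, name = "C",  resName = "ALA", chain = "A", resSeq = 1,
            x = 2.0, y = 1.42, z = 0, element = "C"),
    pdbLine(serial = 4, name = "CB", altLoc = "A", resName = "ALA",
            chain = "A", resSeq = 1, x = 2.0, y = -0.8, z = 1.1, occ = 0.4,
            element = "C"),
    pdbLine(serial = 5, name = "CB", altLoc = "B", resName = "ALA",
            chain = "A", resSeq = 1, x = 2.1, y = -0.9, z = 1.0, occ = 0.6,
            element = "C"),
    pdbLine(serial = 6, name = "HA", resName = "ALA", chain = "A", resSeq = 1,
            x = 1.5, y = -0.5, z = -0.9, element = "H"),
    pdbLine(serial = 7, name = "CA", resName = "GLY", chain = "A", resSeq = 2,
            icode = "A", x = 4.1, y = 2.0, z = 0.3, element = "C"),
    pdbLine(serial = 8, name = "CA", resName = "GLY", chain = "B", resSeq = 1,
            x = 9.0, y = 0, z = 0, element = "C"),
    pdbLine(record = "HETATM", serial = 9, name = "O", resName = "HOH",
            chain = "B", resSeq = 101, x = 12, y = 3, z = 1, element = "O"),
    "END"), collapse = "\n")
}

writeTempPdb <- function(model) {
  f <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
  writePDB(model, f)
  f
}

paperDataPath <- function(name) {
  testthat::test_path("paper-data", name)
}

failMissingPaperData <- function(files) {
  missing <- files[!file.exists(files)]
  testthat::fail(paste0(
    "requires experimentally determined reference inputs that are not ",
    "redistributable within the fixture size budget and cannot be fetched ",
    "in an offline environment; to run this check place the file(s) ",
    paste(basename(missing), collapse = ", "),
    " under tests/testthat/paper-data/"))
}
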