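#' Deterministic spiral point lattice on the unit sphere
#'
#' Golden-angle (Fibonacci) lattice; no random number generator is involved,
#' so every surface-area result is bit-reproducible for a fixed point count.
#'
#' @param n number of points.
#' @return an `n x 3` matrix of unit vectors.
#' @export
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the united-heavy-atom van der Waals surface by
#' the classic test-point method: each atom's expanded sphere (radius
#' `vdW + probe`) carries `nPoints` lattice points, and the accessible area is
#' the exposed fraction times `4 * pi * (r + probe)^2`.  Hydrogens, waters
#' and (by default) hetero atoms are excluded.
#'
#' @param model a [Structure-class].
#' @param radii a [RadiusSet-class].
#' @param probe probe radius in Angstrom (1.4, a water molecule).
#' @param nPoints test points per atom (>= 100); 960 gives within ~1% of
#'   closed-form two-sphere areas.
#' @param includeHetero include non-water HETATM records.
#' @return a [SasaResult-class].
#' @examples
#' fx <- makeTwoSphereFixture(1.7, 1.7, 10)
#' shrakeRupleySasa(fx$model, fx$radii)
#' @export
shrakeRupleySasa <- function(model, radii = defaultRadiusSet(), probe = 1.4,
                             nPoints = 960L, includeHetero = FALSE) {
  stopifnot(is(model, "Structure"))
  if (nPoints < 100) stop("nPoints must be at least 100")
  a <- .proteinHeavyAtoms(model, includeHetero = includeHetero)
  if (nrow(a) == 0) stop("no heavy protein atoms to evaluate")
  r <- atomRadii(a, radii) + probe
  pts <- fibonacciSphere(nPoints)
  area <- .sasaKernel(as.matrix(a[, c("x", "y", "z")]), r, pts)
  resKey <- paste(a$chainId, a$resSeq, a$insert, sep = "\r")
  per <- rowsum(area, resKey, reorder = FALSE)
  first <- !duplicated(resKey)
  residueArea <- data.frame(chainId = a$chainId[first],
                            resSeq = a$resSeq[first],
                            insert = a$insert[first],
                            resName = a$resName[first],
                            area = as.numeric(per[match(unique(resKey),
                                                        rownames(per))]),
                            stringsAsFactors = FALSE)
  new("SasaResult", atoms = a, atomArea = as.numeric(area),
      residueArea = residueArea, total = sum(area), probeRadius = probe,
      nSpherePoints = as.integer(nPoints))
}

.assertDisjoint <- function(selA, selB) {
  keyA <- with(selA@atoms, paste(chainId, resSeq, insert, name))
  keyB <- with(selB@atoms, paste(chainId, resSeq, insert, name))
  if (length(intersect(keyA, keyB)) > 0)
    stop("the two groups overlap; buried surface area requires disjoint groups")
}

.bsaParts <- function(model, groupA, groupB, radii, probe, nPoints) {
  if (is.character(groupA)) groupA <- chainGroup(groupA)
  if (is.character(groupB)) groupB <- chainGroup(groupB)
  selA <- selectAtoms(model, groupA, heavyOnly = TRUE)
  selB <- selectAtoms(model, groupB, heavyOnly = TRUE)
  .assertDisjoint(selA, selB)
  both <- .structureFromAtoms(rbind(selA@atoms, selB@atoms),
                              resolved = model@resolvedAltLocs)
  sA <- shrakeRupleySasa(selA, radii, probe, nPoints)
  sB <- shrakeRupleySasa(selB, radii, probe, nPoints)
  sAB <- shrakeRupleySasa(both, radii, probe, nPoints)
  list(groupA = groupA, groupB = groupB, sA = sA, sB = sB, sAB = sAB,
       nA = nrow(sA@atoms))
}

#' Buried surface area between two chain groups
#'
#' `BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together)`, the total
#' area summed over both sides of the interface (not halved) -- the
#' convention consistent with the dimer-interface values printed for the
#' RapH-Spo0F heterotetramer.
#'
#' @inheritParams shrakeRupleySasa
#' @param groupA,groupB [ChainGroup-class] objects (or spec strings); must be
#'   disjoint.
#' @return total buried area in Angstrom^2, with per-side areas in the
#'   `"sides"` attribute.
#' @export
buriedSurfaceArea <- function(model, groupA, groupB,
                              radii = defaultRadiusSet(), probe = 1.4,
                              nPoints = 960L) {
  p <- .bsaParts(model, groupA, groupB, radii, probe, nPoints)
  dA <- p$sA@total - sum(p$sAB@atomArea[seq_len(p$nA)])
  dB <- p$sB@total - sum(p$sAB@atomArea[-seq_len(p$nA)])
  structure(dA + dB, sides = c(A = dA, B = dB))
}

#' Interface residues by solvent-accessibility loss
#'
#' Computes per-residue delta-SASA (`SASA alone - SASA in complex`) on both
#' sides of a two-group interface and reports the residues whose burial
#' exceeds `threshold` (1 Angstrom^2 by default).
#'
#' @inheritParams buriedSurfaceArea
#' @param threshold per-residue delta-SASA threshold in Angstrom^2.
#' @return an [InterfaceReport-class].
#' @export
interfaceResidues <- function(model, groupA, groupB, threshold = 1.0,
                              radii = defaultRadiusSet(), probe = 1.4,
                              nPoints = 960L) {
  p <- .bsaParts(model, groupA, groupB, radii, probe, nPoints)
  dAtoms <- c(p$sA@atomArea, p$sB@atomArea) - p$sAB@atomArea
  a <- p$sAB@atoms
  side <- rep(c("A", "B"), c(p$nA, nrow(a) - p$nA))
  resKey <- paste(side, a$chainId, a$resSeq, a$insert, sep = "\r")
  per <- rowsum(dAtoms, resKey, reorder = FALSE)
  first <- !duplicated(resKey)
  perResidue <- data.frame(side = side[first],
                           chainId = a$chainId[first],
                           resSeq = a$resSeq[first],
                           insert = a$insert[first],
                           resName = a$resName[first],
                           dsasa = as.numeric(per[match(unique(resKey),
                                                        rownames(per))]),
                           stringsAsFactors = FALSE)
  pick <- function(s) {
    v <- perResidue[perResidue$side == s & perResidue$dsasa > threshold,
                    "resSeq"]
    sort(unique(as.integer(v)))
  }
  new("InterfaceReport", groupA = p$groupA@label, groupB = p$groupB@label,
      totalBsa = sum(perResidue$dsasa), perResidue = perResidue,
      residuesA = pick("A"), residuesB = pick("B"), threshold = threshold)
}

#' Interface residue numbers of one side
#'
#' @param report an [InterfaceReport-class].
#' @param side `"A"` or `"B"`.
#' @return sorted integer vector of author residue numbers.
#' @export
interfaceSide <- function(report, side = c("A", "B")) {
  stopifnot(is(report, "InterfaceReport"))
  side <- match.arg(side)
  if (side == "A") report@residuesA else report@residuesB
}
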