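# -- internal-coordinate side-chain construction ------------------------------
#
# Atoms are placed with the natural extension reference frame (NeRF): given
# three placed atoms A, B, C, atom D is positioned from a bond length |C-D|,
# the bond angle B-C-D and the torsion A-B-C-D.  Side-chain topologies are
# ideal internal coordinates; five- and six-membered rings are laid out with
# fixed planar torsions (closure is ideal-geometry, not refined).

.nerf <- function(A, B, C, bond, angleDeg, torsionDeg) {
  th <- angleDeg * pi / 180
  ph <- torsionDeg * pi / 180
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- .cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("degenerate reference frame in atom placement")
  n <- n / nn
  m <- .cross3(n, bc)
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# topology rows: atom, A, B, C, bond, angle, chi (0 = fixed), offset
.topoRow <- function(atom, A, B, C, bond, angle, chi = 0, offset = 0) {
  list(atom = atom, A = A, B = B, C = C, bond = bond, angle = angle,
       chi = chi, offset = offset)
}

.SIDECHAIN_TOPOLOGY <- list(
  ALA = list(),
  SER = list(.topoRow("OG",  "N",  "CA", "CB", 1.42, 110.8, 1)),
  CYS = list(.topoRow("SG",  "N",  "CA", "CB", 1.81, 113.8, 1)),
  THR = list(.topoRow("OG1", "N",  "CA", "CB", 1.43, 109.6, 1),
             .topoRow("CG2", "N",  "CA", "CB", 1.52, 110.5, 1, -120)),
  VAL = list(.topoRow("CG1", "N",  "CA", "CB", 1.52, 110.5, 1),
             .topoRow("CG2", "N",  "CA", "CB", 1.52, 110.5, 1, 122)),
  ILE = list(.topoRow("CG1", "N",  "CA", "CB", 1.53, 110.4, 1),
             .topoRow("CG2", "N",  "CA", "CB", 1.52, 110.5, 1, -122),
             .topoRow("CD1", "CA", "CB", "CG1", 1.52, 113.8, 2)),
  LEU = list(.topoRow("CG",  "N",  "CA", "CB", 1.53, 116.3, 1),
             .topoRow("CD1", "CA", "CB", "CG", 1.52, 110.5, 2),
             .topoRow("CD2", "CA", "CB", "CG", 1.52, 110.5, 2, 122)),
  ASP = list(.topoRow("CG",  "N",  "CA", "CB", 1.52, 112.6, 1),
             .topoRow("OD1", "CA", "CB", "CG", 1.25, 118.4, 2),
             .topoRow("OD2", "CA", "CB", "CG", 1.25, 118.4, 2, 180)),
  ASN = list(.topoRow("CG",  "N",  "CA", "CB", 1.52, 112.6, 1),
             .topoRow("OD1", "CA", "CB", "CG", 1.23, 120.8, 2),
             .topoRow("ND2", "CA", "CB", "CG", 1.33, 116.4, 2, 180)),
  GLU = list(.topoRow("CG",  "N",  "CA", "CB", 1.52, 114.1, 1),
             .topoRow("CD",  "CA", "CB", "CG", 1.52, 112.6, 2),
             .topoRow("OE1", "CB", "CG", "CD", 1.25, 118.4, 3),
             .topoRow("OE2", "CB", "CG", "CD", 1.25, 118.4, 3, 180)),
  GLN = list(.topoRow("CG",  "N",  "CA", "CB", 1.52, 114.1, 1),
             .topoRow("CD",  "CA", "CB", "CG", 1.52, 112.6, 2),
             .topoRow("OE1", "CB", "CG", "CD", 1.23, 120.8, 3),
             .topoRow("NE2", "CB", "CG", "CD", 1.33, 116.4, 3, 180)),
  MET = list(.topoRow("CG",  "N",  "CA", "CB", 1.52, 114.1, 1),
             .topoRow("SD",  "CA", "CB", "CG", 1.80, 112.7, 2),
             .topoRow("CE",  "CB", "CG", "SD", 1.79, 100.2, 3)),
  LYS = list(.topoRow("CG",  "N",  "CA", "CB", 1.52, 114.1, 1),
             .topoRow("CD",  "CA", "CB", "CG", 1.52, 111.3, 2),
             .topoRow("CE",  "CB", "CG", "CD", 1.52, 111.3, 3),
             .topoRow("NZ",  "CG", "CD", "CE", 1.49, 111.9, 4)),
  ARG = list(.topoRow("CG",  "N",  "CA", "CB", 1.52, 114.1, 1),
             .topoRow("CD",  "CA", "CB", "CG", 1.52, 111.3, 2),
             .topoRow("NE",  "CB", "CG", "CD", 1.46, 111.9, 3),
             .topoRow("CZ",  "CG", "CD", "NE", 1.33, 124.2, 4),
             .topoRow("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0, 0),
             .topoRow("NH2", "CD", "NE", "CZ", 1.33, 120.0, 0, 180)),
  HIS = list(.topoRow("CG",  "N",  "CA", "CB", 1.50, 113.8, 1),
             .topoRow("ND1", "CA", "CB", "CG", 1.38, 122.7, 2),
             .topoRow("CD2", "CA", "CB", "CG", 1.36, 129.7, 2, 180),
             .topoRow("CE1", "CB", "CG", "ND1", 1.32, 109.2, 0, 180),
             .topoRow("NE2", "CB", "CG", "CD2", 1.37, 107.2, 0, 180)),
  PHE = list(.topoRow("CG",  "N",  "CA", "CB", 1.50, 113.8, 1),
             .topoRow("CD1", "CA", "CB", "CG", 1.39, 120.8, 2),
             .topoRow("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
             .topoRow("CE1", "CB", "CG", "CD1", 1.39, 120.0, 0, 180),
             .topoRow("CE2", "CB", "CG", "CD2", 1.39, 120.0, 0, 180),
             .topoRow("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0, 0)),
  TYR = list(.topoRow("CG",  "N",  "CA", "CB", 1.50, 113.8, 1),
             .topoRow("CD1", "CA", "CB", "CG", 1.39, 120.8, 2),
             .topoRow("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
             .topoRow("CE1", "CB", "CG", "CD1", 1.39, 120.0, 0, 180),
             .topoRow("CE2", "CB", "CG", "CD2", 1.39, 120.0, 0, 180),
             .topoRow("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0, 0),
             .topoRow("OH",  "CD1", "CE1", "CZ", 1.38, 120.0, 0, 180)),
  TRP = list(.topoRow("CG",  "N",  "CA", "CB", 1.50, 113.8, 1),
             .topoRow("CD1", "CA", "CB", "CG", 1.37, 127.0, 2),
             .topoRow("CD2", "CA", "CB", "CG", 1.43, 126.6, 2, 180),
             .topoRow("NE1", "CB", "CG", "CD1", 1.38, 110.2, 0, 180),
             .topoRow("CE2", "CB", "CG", "CD2", 1.41, 107.2, 0, 180),
             .topoRow("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0, 0),
             .topoRow("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 0, 180),
             .topoRow("CZ3", "CG", "CD2", "CE3", 1.39, 118.8, 0, 180),
             .topoRow("CH2", "CD2", "CE3", "CZ3", 1.37, 117.5, 0, 0))
)

.t <- function(...) c(...)   # terse chi tuple
.m <- -60; .p <- 60; .tt <- 180

# Canonical modal chi-angle library (penultimate-style means).  His carries 8
# rotamers; Lys is capped to the 12 most common of its 27; Leu has 4.
.ROTAMER_LIBRARY <- list(
  GLY = matrix(numeric(0), nrow = 1, ncol = 0),
  ALA = matrix(numeric(0), nrow = 1, ncol = 0),
  SER = cbind(c(.m, .tt, .p)),
  CYS = cbind(c(.m, .tt, .p)),
  THR = cbind(c(.m, .tt, .p)),
  VAL = cbind(c(.tt, .m, .p)),
  ILE = rbind(.t(.m, 170), .t(.m, .m), .t(.tt, 165), .t(.p, 170)),
  LEU = rbind(.t(.m, .tt), .t(.tt, .p), .t(.tt, .tt), .t(.m, .p)),
  ASP = rbind(.t(.m, -15), .t(.m, 65), .t(.tt, 0), .t(.tt, 65), .t(.p, -15)),
  ASN = rbind(.t(.m, -20), .t(.m, 120), .t(.tt, -60), .t(.tt, 60),
              .t(.p, -20), .t(.p, 120)),
  GLU = rbind(.t(.m, .tt, 0), .t(.m, .m, -40), .t(.tt, .tt, 0),
              .t(.tt, .p, 60), .t(.p, .tt, 0), .t(.m, .p, 0)),
  GLN = rbind(.t(.m, .tt, 0), .t(.m, .m, -40), .t(.tt, .tt, 0),
              .t(.tt, .p, 60), .t(.p, .tt, 0), .t(.m, .p, 0)),
  MET = rbind(.t(.m, .tt, .tt), .t(.m, .m, .m), .t(.m, .tt, .p),
              .t(.tt, .tt, .tt), .t(.tt, .p, .p), .t(.p, .tt, .tt),
              .t(.m, .m, .tt), .t(.tt, .tt, .p)),
  LYS = rbind(.t(.tt, .tt, .tt, .tt), .t(.m, .tt, .tt, .tt),
              .t(.tt, .tt, .tt, .m), .t(.tt, .tt, .tt, .p),
              .t(.m, .tt, .tt, .m), .t(.m, .tt, .tt, .p),
              .t(.tt, .tt, .m, .tt), .t(.tt, .m, .tt, .tt),
              .t(.m, .m, .tt, .tt), .t(.tt, .tt, .p, .tt),
              .t(.tt, .p, .tt, .tt), .t(.p, .tt, .tt, .tt)),
  ARG = rbind(.t(.tt, .tt, .tt, .tt), .t(.m, .tt, .tt, .tt),
              .t(.m, .tt, .tt, .m), .t(.tt, .tt, .tt, .p),
              .t(.m, .m, .tt, .tt), .t(.tt, .tt, .m, .tt),
              .t(.tt, .p, .tt, .tt), .t(.p, .tt, .tt, .tt)),
  HIS = rbind(.t(.m, -70), .t(.m, 80), .t(.m, 165), .t(.tt, -165),
              .t(.tt, -80), .t(.tt, 60), .t(.p, -75), .t(.p, 80)),
  PHE = rbind(.t(.m, 90), .t(.tt, 80), .t(.p, 90), .t(.m, -85)),
  TYR = rbind(.t(.m, 90), .t(.tt, 80), .t(.p, 90), .t(.m, -85)),
  TRP = rbind(.t(.m, 95), .t(.m, -5), .t(.tt, -105), .t(.tt, 90),
              .t(.p, -90))
)

#' Canonical side-chain rotamer library
#'
#' Modal chi-angle combinations per residue type, fixed and versioned with
#' the package, together with the ideal internal coordinates used to build
#' side chains on a fixed backbone.  Proline is not supported (its side chain
#' closes onto the backbone and cannot be swept as independent torsions).
#'
#' @return named list: one numeric matrix per residue type, one rotamer per
#'   row, one chi angle (degrees, in (-180, 180]) per column.
#' @export
defaultRotamerLibrary <- function() .ROTAMER_LIBRARY

#' Residue types supported by the side-chain builder
#' @return character vector of three-letter codes.
#' @export
supportedResidues <- function() names(.ROTAMER_LIBRARY)

# ideal CB from backbone N, CA, C (used when the target residue is glycine)
.idealCB <- function(N, CA, C) .nerf(C, N, CA, 1.53, 110.5, 122.5)

#' Build a side chain on a fixed backbone
#'
#' Places side-chain atoms beyond C-beta with ideal internal coordinates at
#' the requested chi angles.  C-beta is taken from the backbone when present
#' and constructed ideally otherwise (always for a glycine target).
#'
#' @param resName three-letter code of the residue to build.
#' @param backbone named list of length-3 coordinate vectors: `N`, `CA`, `C`
#'   required, `CB` optional.
#' @param chis numeric vector of chi angles in degrees (length must match the
#'   residue's chi count).
#' @return named list of coordinates for `CB` and all atoms beyond it.
#' @export
buildSideChain <- function(resName, backbone, chis = numeric(0)) {
  resName <- toupper(resName)
  if (!resName %in% names(.SIDECHAIN_TOPOLOGY) && resName != "GLY")
    stop("unsupported residue type: ", resName)
  for (at in c("N", "CA", "C"))
    if (is.null(backbone[[at]]))
      stop("backbone atom ", at, " required to build a side chain")
  placed <- backbone
  if (is.null(placed$CB))
    placed$CB <- .idealCB(placed$N, placed$CA, placed$C)
  out <- list()
  if (resName == "GLY") return(out)
  out$CB <- placed$CB
  topo <- .SIDECHAIN_TOPOLOGY[[resName]]
  nchi <- if (length(topo) == 0) 0 else max(vapply(topo, `[[`, 0, "chi"))
  if (length(chis) < nchi)
    stop(resName, " needs ", nchi, " chi angle(s), got ", length(chis))
  for (row in topo) {
    tors <- if (row$chi > 0) chis[row$chi] + row$offset else row$offset
    placed[[row$atom]] <- .nerf(placed[[row$A]], placed[[row$B]],
                                placed[[row$C]], row$bond, row$angle, tors)
    out[[row$atom]] <- placed[[row$atom]]
  }
  out
}

# -- ideal extended backbone (used for reference peptides and fixtures) -------

# Returns a list of residues; each residue is a named list of backbone atom
# coordinates N, CA, C, O in an extended (phi = psi = 180) conformation.
.extendedBackbone <- function(n) {
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- .nerf(c(0, 1, 0), N, CA, 1.525, 111.0, 180)  # seed frame
  res[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n)[-1]) {
    prev <- res[[i - 1]]
    N <- .nerf(prev$N, prev$CA, prev$C, 1.33, 116.2, 180)   # psi
    CA <- .nerf(prev$CA, prev$C, N, 1.458, 121.7, 180)      # omega
    C <- .nerf(prev$C, N, CA, 1.525, 111.0, 180)            # phi
    res[[i]] <- list(N = N, CA = CA, C = C)
  }
  for (i in seq_len(n)) {
    nxt <- if (i < n) res[[i + 1]]$N else NULL
    res[[i]]$O <- if (is.null(nxt))
      .nerf(res[[i]]$N, res[[i]]$CA, res[[i]]$C, 1.23, 120.5, 0)
    else
      .nerf(nxt, res[[i]]$CA, res[[i]]$C, 1.23, 120.5, 180)
  }
  res
}

# Assemble a Structure from a list of residues given as
# list(resSeq=, resName=, chainId=, atoms=named list of coords, hetero=)
.structureFromResidues <- function(residues, title = "") {
  rows <- list()
  serial <- 0L
  for (r in residues) {
    het <- isTRUE(r$hetero)
    for (nm in names(r$atoms)) {
      serial <- serial + 1L
      el <- sub("^[0-9']+", "", nm)
      el <- substr(el, 1, 1)
      rows[[serial]] <- data.frame(
        serial = serial, name = nm, altLoc = "", resName = r$resName,
        chainId = r$chainId, resSeq = as.integer(r$resSeq), insert = "",
        x = r$atoms[[nm]][1], y = r$atoms[[nm]][2], z = r$atoms[[nm]][3],
        occupancy = 1, bFactor = 0, element = el, isHetero = het,
        stringsAsFactors = FALSE)
    }
  }
  .structureFromAtoms(do.call(rbind, rows), title = title)
}

# cache for reference side-chain areas (Gly-X-Gly extended peptide)
.rapspecCache <- new.env(parent = emptyenv())

#' Reference side-chain accessibility in a Gly-X-Gly extended peptide
#'
#' Builds an extended Gly-X-Gly tripeptide with the residue of interest in
#' the middle (chi1 = 180 and otherwise modal angles), and returns the summed
#' solvent-accessible area of its side-chain atoms (C-beta and beyond).  Used
#' as the denominator of relative side-chain SASA in the His switch
#' classifier.
#'
#' @param resName three-letter code.
#' @param radii a [RadiusSet-class].
#' @param probe probe radius, Angstrom.
#' @param nPoints sphere points.
#' @return reference area in Angstrom^2 (cached per parameter combination).
#' @export
referenceSideChainArea <- function(resName, radii = defaultRadiusSet(),
                                   probe = 1.4, nPoints = 960L) {
  resName <- toupper(resName)
  key <- paste(resName, radii@name, probe, nPoints, sep = "|")
  if (!is.null(.rapspecCache[[key]])) return(.rapspecCache[[key]])
  bb <- .extendedBackbone(3)
  lib <- defaultRotamerLibrary()
  if (!resName %in% names(lib))
    stop("unsupported residue type: ", resName)
  nchi <- ncol(lib[[resName]])
  chis <- if (nchi == 0) numeric(0) else c(180, rep(-80, nchi - 1))
  side <- buildSideChain(resName, bb[[2]], chis)
  residues <- list(
    list(resSeq = 1, resName = "GLY", chainId = "X", atoms = bb[[1]]),
    list(resSeq = 2, resName = resName, chainId = "X",
         atoms = c(bb[[2]], side)),
    list(resSeq = 3, resName = "GLY", chainId = "X", atoms = bb[[3]]))
  model <- .structureFromResidues(residues)
  sasa <- shrakeRupleySasa(model, radii, probe, nPoints)
  sel <- sasa@atoms$resSeq == 2 &
    !(sasa@atoms$name %in% c("N", "CA", "C", "O"))
  val <- sum(sasa@atomArea[sel])
  .rapspecCache[[key]] <- val
  val
}
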