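#' @import methods
NULL

.ATOM_COLS <- c("serial", "name", "altLoc", "resName", "chainId", "resSeq",
                "insert", "x", "y", "z", "occupancy", "bFactor", "element",
                "isHetero")

#' Atomic coordinate model
#'
#' A `Structure` holds a flat atom table (one row per atom) grouped
#' hierarchically by chain, residue and atom name, with author residue
#' numbering and insertion codes preserved exactly as deposited.  It is the
#' container consumed by every geometric, surface and mutational operation in
#' the package.
#'
#' @slot atoms `data.frame` with columns `serial`, `name`, `altLoc`,
#'   `resName`, `chainId`, `resSeq`, `insert`, `x`, `y`, `z`, `occupancy`,
#'   `bFactor`, `element`, `isHetero`.
#' @slot title character, free-text description carried from the source file.
#' @slot resolvedAltLocs logical; `TRUE` once alternate locations have been
#'   reduced to a single conformer per atom (see [resolveAltLocs()]).
#'
#' @seealso [readPDB()], [selectAtoms()], [resolveAltLocs()]
#' @exportClass Structure
setClass("Structure",
         representation(atoms = "data.frame",
                        title = "character",
                        resolvedAltLocs = "logical"),
         prototype(title = "", resolvedAltLocs = FALSE))

setValidity("Structure", function(object) {
  a <- object@atoms
  missing <- setdiff(.ATOM_COLS, names(a))
  if (length(missing) > 0)
    return(paste("atom table lacks columns:", paste(missing, collapse = ", ")))
  if (nrow(a) == 0) return(TRUE)
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite atomic coordinates")
  if (any(is.na(a$occupancy)) || any(a$occupancy < 0 | a$occupancy > 1))
    return("occupancy outside [0, 1]")
  if (any(!nzchar(a$element)))
    return("empty element symbol")
  if (isTRUE(object@resolvedAltLocs)) {
    key <- paste(a$chainId, a$resSeq, a$insert, a$name)
    if (anyDuplicated(key))
      return("duplicate (residue, atom name) after alt-loc resolution")
  }
  TRUE
})

#' Named selection of chains and residue ranges
#'
#' A `ChainGroup` labels a molecular unit (for example one Rap copy or its
#' N-terminal three-helix bundle) as a set of chain identifiers with optional
#' author-numbering residue ranges.  Which deposited chain corresponds to
#' which biological molecule is user configuration, never hard-coded.
#'
#' @slot label character label, e.g. `"RapH_A"`.
#' @slot chains character vector of chain identifiers.
#' @slot ranges named list, one entry per chain: either `NULL` (whole chain)
#'   or an integer vector of residue numbers.
#'
#' @seealso [chainGroup()]
#' @exportClass ChainGroup
setClass("ChainGroup",
         representation(label = "character", chains = "character",
                        ranges = "list"))

setValidity("ChainGroup", function(object) {
  if (length(object@chains) == 0) return("empty chain set")
  if (length(object@ranges) != length(object@chains))
    return("ranges must have one entry per chain")
  TRUE
})

#' Residue correspondence between two chains
#'
#' Ordered residue pairs used for superposition, built either from shared
#' author numbering (same protein in two crystallographic copies) or from an
#' explicit user-supplied pair list for heterologous proteins.
#'
#' @slot pairs `data.frame` with columns `mobileRes` and `refRes` (author
#'   residue numbers).
#' @slot mobileChain,refChain chain identifiers.
#' @slot atomName atom used for pairing (default `"CA"`).
#' @exportClass CorrespondenceMap
setClass("CorrespondenceMap",
         representation(pairs = "data.frame", mobileChain = "character",
                        refChain = "character", atomName = "character"))

setValidity("CorrespondenceMap", function(object) {
  p <- object@pairs
  if (!all(c("mobileRes", "refRes") %in% names(p)))
    return("pairs needs columns mobileRes, refRes")
  if (anyDuplicated(p$mobileRes) || anyDuplicated(p$refRes))
    return("a residue appears twice in the correspondence")
  if (nrow(p) < 3) return("need at least 3 residue pairs")
  TRUE
})

#' Rigid-body superposition result
#'
#' @slot rotation 3x3 proper orthonormal matrix mapping centred mobile
#'   coordinates onto the reference frame.
#' @slot translation length-3 numeric, Angstrom.
#' @slot rmsd root-mean-square deviation over the paired atoms after the
#'   optimal transform, Angstrom.
#' @slot nPairs number of atom pairs used.
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
         representation(rotation = "matrix", translation = "numeric",
                        rmsd = "numeric", nPairs = "integer"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(t(R) %*% R - diag(3))) > 1e-8) return("rotation not orthonormal")
  if (det(R) < 0) return("improper rotation (det < 0)")
  if (object@rmsd < 0) return("negative rmsd")
  TRUE
})

#' Van der Waals radius assignment
#'
#' United-heavy-atom radius set in the Chothia/NACCESS tradition: element
#' fallbacks plus a reduced radius for trigonal (sp2) carbons such as backbone
#' carbonyls, aromatic rings and carboxylate/amide carbons.  Per-atom
#' overrides keyed `"RESNAME:ATOMNAME"` allow analytic fixtures with arbitrary
#' radii.
#'
#' @slot name character name of the set.
#' @slot elementRadii named numeric, Angstrom; must define C, N, O, S, P.
#' @slot trigonalCarbon numeric radius used for sp2 carbons.
#' @slot trigonalAtoms character vector of `"RESNAME:ATOMNAME"` keys treated
#'   as trigonal carbons (backbone `C` is always trigonal).
#' @slot atomRadii named numeric of `"RESNAME:ATOMNAME"` overrides.
#' @exportClass RadiusSet
setClass("RadiusSet",
         representation(name = "character", elementRadii = "numeric",
                        trigonalCarbon = "numeric", trigonalAtoms = "character",
                        atomRadii = "numeric"))

setValidity("RadiusSet", function(object) {
  need <- c("C", "N", "O", "S", "P")
  if (!all(need %in% names(object@elementRadii)))
    return("element fallback radii must cover C, N, O, S, P")
  r <- c(object@elementRadii, object@trigonalCarbon, object@atomRadii)
  if (any(r < 1.0 | r > 2.5))
    return("all radii must lie in [1.0, 2.5] Angstrom")
  TRUE
})

#' Solvent-accessible surface area result
#'
#' @slot atoms atom table of the (heavy) atoms the calculation used.
#' @slot atomArea numeric, per-atom accessible area, Angstrom^2.
#' @slot residueArea `data.frame` of per-residue sums.
#' @slot total total accessible area, Angstrom^2.
#' @slot probeRadius probe radius used, Angstrom.
#' @slot nSpherePoints number of test points per atom.
#' @exportClass SasaResult
setClass("SasaResult",
         representation(atoms = "data.frame", atomArea = "numeric",
                        residueArea = "data.frame", total = "numeric",
                        probeRadius = "numeric", nSpherePoints = "integer"))

setValidity("SasaResult", function(object) {
  if (any(object@atomArea < 0)) return("negative atom area")
  if (nrow(object@atoms) != length(object@atomArea))
    return("atomArea length does not match atom table")
  if (abs(sum(object@atomArea) - object@total) > 1e-6 * max(1, object@total))
    return("total does not equal sum of atom areas")
  TRUE
})

#' Protein-protein interface report
#'
#' Per-residue solvent-accessibility loss (delta-SASA) on both sides of a
#' two-group interface, the total buried surface area, and the residue lists
#' passing the delta-SASA threshold.
#'
#' @slot groupA,groupB labels of the two sides.
#' @slot totalBsa total buried surface area summed over both sides,
#'   Angstrom^2.
#' @slot perResidue `data.frame` with columns `side`, `chainId`, `resSeq`,
#'   `insert`, `resName`, `dsasa`.
#' @slot residuesA,residuesB integer vectors of author residue numbers with
#'   `dsasa` above the threshold, sorted.
#' @slot threshold delta-SASA threshold, Angstrom^2.
#' @exportClass InterfaceReport
setClass("InterfaceReport",
         representation(groupA = "character", groupB = "character",
                        totalBsa = "numeric", perResidue = "data.frame",
                        residuesA = "integer", residuesB = "integer",
                        threshold = "numeric"))

setValidity("InterfaceReport", function(object) {
  if (object@totalBsa < -1e-9) return("negative buried surface area")
  if (abs(sum(object@perResidue$dsasa) - object@totalBsa) > 1e-3)
    return("per-residue delta-SASA does not sum to the total BSA")
  TRUE
})

#' Multiple sequence alignment profile
#'
#' Aligned sequences as a character matrix plus the mapping from alignment
#' columns to positions of a named reference sequence (RapH numbering in the
#' study system).
#'
#' @slot ids sequence identifiers (row order of `aln`).
#' @slot aln character matrix, one row per sequence, one column per aligned
#'   position; gaps are `"-"`.
#' @slot referenceId identifier of the reference sequence.
#' @slot referenceMap integer vector, one entry per column: the reference
#'   position, or `NA` where the reference has a gap.
#' @exportClass MsaProfile
setClass("MsaProfile",
         representation(ids = "character", aln = "matrix",
                        referenceId = "character", referenceMap = "integer"))

setValidity("MsaProfile", function(object) {
  if (nrow(object@aln) != length(object@ids)) return("ids/aln mismatch")
  if (nrow(object@aln) < 2) return("need at least 2 sequences")
  if (!object@referenceId %in% object@ids) return("reference id not present")
  if (length(object@referenceMap) != ncol(object@aln))
    return("referenceMap length must equal alignment width")
  m <- object@referenceMap[!is.na(object@referenceMap)]
  if (length(m) > 1 && any(diff(m) <= 0))
    return("referenceMap must be strictly increasing over non-gap columns")
  TRUE
})

#' Conserved interfacial position set
#'
#' Reference-numbered alignment columns that are both highly conserved across
#' the phosphatase training set and buried in the complex interface.
#'
#' @slot positions integer vector of reference (RapH) positions, sorted.
#' @slot scores named numeric conservation scores in `[0, 1]`, one per
#'   position.
#' @slot threshold conservation threshold used.
#' @slot trainingIds identifiers of the training phosphatases.
#' @exportClass ConservedPositionSet
setClass("ConservedPositionSet",
         representation(positions = "integer", scores = "numeric",
                        threshold = "numeric", trainingIds = "character"))

setValidity("ConservedPositionSet", function(object) {
  if (length(object@scores) != length(object@positions))
    return("one score per position required")
  if (length(object@scores) > 0 &&
      any(object@scores < 0 | object@scores > 1))
    return("scores must lie in [0, 1]")
  TRUE
})

#' Identity score of a candidate at the conserved interfacial positions
#'
#' @slot candidateId candidate sequence identifier.
#' @slot nMatch number of positions where the candidate residue is identical
#'   to that of at least one training phosphatase.
#' @slot nTotal number of scored positions.
#' @slot mismatches `data.frame` with columns `position`, `candidate`,
#'   `training`.
#' @exportClass CandidateScore
setClass("CandidateScore",
         representation(candidateId = "character", nMatch = "integer",
                        nTotal = "integer", mismatches = "data.frame"))

setValidity("CandidateScore", function(object) {
  if (object@nMatch < 0 || object@nMatch > object@nTotal)
    return("nMatch outside [0, nTotal]")
  if (nrow(object@mismatches) != object@nTotal - object@nMatch)
    return("mismatch rows must equal nTotal - nMatch")
  TRUE
})

#' Rotamer clash scan of a point substitution
#'
#' @slot chainId,position,insert identify the mutated residue.
#' @slot newResidue three-letter code of the modeled residue.
#' @slot rotamerOverlaps numeric, worst steric overlap (Angstrom) per rotamer;
#'   a value below the cutoff means the rotamer fits.
#' @slot clashFreeFraction fraction of rotamers whose worst overlap is at or
#'   below the cutoff.
#' @slot overlapCutoff Angstrom.
#' @exportClass ClashReport
setClass("ClashReport",
         representation(chainId = "character", position = "integer",
                        insert = "character", newResidue = "character",
                        rotamerOverlaps = "numeric",
                        clashFreeFraction = "numeric",
                        overlapCutoff = "numeric"))

setValidity("ClashReport", function(object) {
  f <- object@clashFreeFraction
  if (f < 0 || f > 1) return("clashFreeFraction outside [0, 1]")
  n <- length(object@rotamerOverlaps)
  if (n > 0) {
    expect <- mean(object@rotamerOverlaps <= object@overlapCutoff)
    if (abs(expect - f) > 1e-12)
      return("clashFreeFraction inconsistent with rotamer overlaps")
  }
  TRUE
})

#' Rule-based phosphatase verdict
#'
#' @slot candidateId candidate sequence identifier.
#' @slot call one of `"phosphatase"`, `"non-phosphatase"`, `"indeterminate"`.
#' @slot identityFraction nMatch / nTotal.
#' @slot nMatch,nTotal identity counts.
#' @slot catalyticPass logical, Gln/Glu at the catalytic position.
#' @slot catalyticResidue residue found at the catalytic position.
#' @slot blockedPositions mismatch positions whose every rotamer clashes.
#' @slot mismatches the candidate's mismatch table.
#' @slot thresholds list of thresholds used (full provenance).
#' @exportClass SpecificityVerdict
setClass("SpecificityVerdict",
         representation(candidateId = "character", call = "character",
                        identityFraction = "numeric", nMatch = "integer",
                        nTotal = "integer", catalyticPass = "logical",
                        catalyticResidue = "character",
                        blockedPositions = "integer",
                        mismatches = "data.frame", thresholds = "list"))

setValidity("SpecificityVerdict", function(object) {
  if (!object@call %in% c("phosphatase", "non-phosphatase", "indeterminate"))
    return("invalid call")
  TRUE
})

#' Receiver-domain switch-state report
#'
#' @slot chainId receiver chain examined.
#' @slot thrOrientation `"toward"`, `"away"` or `"indeterminate"`.
#' @slot hisEnvironment `"internal"`, `"external"` or `"indeterminate"`.
#' @slot loopAngle beta4-alpha4 loop pseudodihedral in degrees, or `NA` when
#'   the loop is disordered.
#' @slot overall `"phosphorylated-like"`, `"non-phosphorylated-like"` or
#'   `"mixed"`.
#' @exportClass SwitchStateReport
setClass("SwitchStateReport",
         representation(chainId = "character", thrOrientation = "character",
                        hisEnvironment = "character", loopAngle = "numeric",
                        overall = "character"))

setValidity("SwitchStateReport", function(object) {
  ok <- (object@thrOrientation == "toward" &&
         object@hisEnvironment == "internal" &&
         object@overall == "phosphorylated-like") ||
        (object@thrOrientation == "away" &&
         object@hisEnvironment == "external" &&
         object@overall == "non-phosphorylated-like") ||
        object@overall == "mixed"
  if (!ok) return("overall label inconsistent with switch axes")
  TRUE
})
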