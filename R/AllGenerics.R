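#' Accessors for rapspec objects
#'
#' Small accessor generics so that slot layout stays an implementation
#' detail: `atoms()` returns the atom table of a [Structure-class],
#' `chainIds()` the chain identifiers, `nAtoms()` the atom count.
#'
#' @param x an object.
#' @return `atoms()`: a `data.frame`; `chainIds()`: character; `nAtoms()`:
#'   integer.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setMethod("atoms", "Structure", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("chainIds", "Structure", function(x) unique(x@atoms$chainId))

#' @rdname accessors
#' @export
setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  res <- unique(paste(a$chainId, a$resSeq, a$insert))
  cat("Structure:", nrow(a), "atoms,", length(res), "residues,",
      length(unique(a$chainId)), "chain(s)",
      if (isTRUE(object@resolvedAltLocs)) "[alt-locs resolved]" else "", "\n")
  if (nzchar(object@title)) cat("  title:", object@title, "\n")
  cat("  chains:", paste(unique(a$chainId), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "ChainGroup", function(object) {
  rng <- vapply(seq_along(object@chains), function(i) {
    r <- object@ranges[[i]]
    if (is.null(r)) object@chains[i]
    else paste0(object@chains[i], ":", min(r), "-", max(r))
  }, character(1))
  cat("ChainGroup", shQuote(object@label), "->",
      paste(rng, collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("Superposition over %d pairs: rmsd %.3f A\n",
              object@nPairs, object@rmsd))
  invisible(object)
})

setMethod("show", "SasaResult", function(object) {
  cat(sprintf("SASA: %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              object@total, nrow(object@atoms), object@probeRadius,
              object@nSpherePoints))
  invisible(object)
})

setMethod("show", "InterfaceReport", function(object) {
  cat(sprintf("Interface %s | %s: total BSA %.1f A^2\n",
              object@groupA, object@groupB, object@totalBsa))
  cat(sprintf("  %d residues on side A, %d on side B above %.2f A^2\n",
              length(object@residuesA), length(object@residuesB),
              object@threshold))
  invisible(object)
})

setMethod("show", "MsaProfile", function(object) {
  cat(sprintf("MsaProfile: %d sequences x %d columns (reference %s)\n",
              nrow(object@aln), ncol(object@aln), object@referenceId))
  invisible(object)
})

setMethod("show", "ConservedPositionSet", function(object) {
  cat(sprintf("%d conserved interfacial positions (threshold %.3f):\n",
              length(object@positions), object@threshold))
  cat(" ", paste(object@positions, collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "CandidateScore", function(object) {
  cat(sprintf("%s: %d/%d conserved interfacial positions matched\n",
              object@candidateId, object@nMatch, object@nTotal))
  if (nrow(object@mismatches) > 0) {
    cat("  mismatches at:",
        paste(object@mismatches$position, collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "ClashReport", function(object) {
  cat(sprintf("%s%d -> %s: clash-free fraction %.2f (%d rotamers, cutoff %.2f A)\n",
              object@chainId, object@position, object@newResidue,
              object@clashFreeFraction,
              max(1L, length(object@rotamerOverlaps)), object@overlapCutoff))
  invisible(object)
})

setMethod("show", "SpecificityVerdict", function(object) {
  cat(sprintf("%s: %s (identity %d/%d, catalytic %s [%s]%s)\n",
              object@candidateId, object@call, object@nMatch, object@nTotal,
              if (object@catalyticPass) "pass" else "fail",
              object@catalyticResidue,
              if (length(object@blockedPositions) > 0)
                paste0(", clash-blocked at ",
                       paste(object@blockedPositions, collapse = ","))
              else ""))
  invisible(object)
})

setMethod("show", "SwitchStateReport", function(object) {
  cat(sprintf("Chain %s: %s (Thr switch %s, His switch %s, loop %s)\n",
              object@chainId, object@overall, object@thrOrientation,
              object@hisEnvironment,
              if (is.na(object@loopAngle)) "disordered"
              else sprintf("%.1f deg", object@loopAngle)))
  invisible(object)
})
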