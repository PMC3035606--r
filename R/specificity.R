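#' Score a candidate Rap sequence at the conserved interfacial positions
#'
#' A position counts as a match when the candidate residue is strictly
#' identical to the residue of at least one training phosphatase at that
#' position (similarity is deliberately not used).  A candidate gap at a
#' scored position is a mismatch.
#'
#' @param candidateId sequence id of the candidate (a warning is issued if it
#'   is also in the training set, since that makes the evaluation circular).
#' @param profile an [MsaProfile-class].
#' @param positions a [ConservedPositionSet-class].
#' @param trainingIds the training phosphatase ids.
#' @return a [CandidateScore-class].
#' @export
scoreCandidate <- function(candidateId, profile, positions, trainingIds) {
  stopifnot(is(profile, "MsaProfile"), is(positions, "ConservedPositionSet"))
  if (!candidateId %in% profile@ids)
    stop("no sequence named ", candidateId, " in the alignment")
  if (candidateId %in% trainingIds)
    warning("candidate ", candidateId,
            " is part of the training set; the evaluation is not independent")
  pos <- positions@positions
  nTotal <- length(pos)
  if (nTotal == 0)
    return(new("CandidateScore", candidateId = candidateId, nMatch = 0L,
               nTotal = 0L,
               mismatches = data.frame(position = integer(0),
                                       candidate = character(0),
                                       training = character(0))))
  cols <- .columnOf(profile, pos)
  cand <- profile@aln[candidateId, cols]
  train <- profile@aln[trainingIds, cols, drop = FALSE]
  match <- logical(nTotal)
  trainingStr <- character(nTotal)
  for (k in seq_len(nTotal)) {
    seen <- setdiff(unique(train[, k]), "-")
    trainingStr[k] <- paste(sort(seen), collapse = "/")
    match[k] <- cand[k] != "-" && cand[k] %in% seen
  }
  mm <- data.frame(position = pos[!match], candidate = cand[!match],
                   training = trainingStr[!match], stringsAsFactors = FALSE)
  rownames(mm) <- NULL
  new("CandidateScore", candidateId = candidateId,
      nMatch = as.integer(sum(match)), nTotal = as.integer(nTotal),
      mismatches = mm)
}

#' Catalytic glutamine/glutamate check
#'
#' Rap-mediated Spo0F dephosphorylation requires Gln or Glu at the position
#' equivalent to RapH Gln47 (the side chain that orients the attacking
#' water); any other residue -- or a gap -- fails.
#'
#' @param candidateId sequence id.
#' @param profile an [MsaProfile-class].
#' @param catalyticPosition reference-numbered catalytic position (RapH 47).
#' @return list with elements `pass` (logical), `residue` (one-letter code or
#'   `"-"`), `position`.
#' @export
catalyticCheck <- function(candidateId, profile, catalyticPosition = 47L) {
  stopifnot(is(profile, "MsaProfile"))
  if (!candidateId %in% profile@ids)
    stop("no sequence named ", candidateId, " in the alignment")
  col <- .columnOf(profile, catalyticPosition)
  res <- unname(profile@aln[candidateId, col])
  list(pass = res %in% c("Q", "E"), residue = res,
       position = as.integer(catalyticPosition))
}

#' Rotamer clash scan of a point substitution
#'
#' Models `newResidue` at a position of the structure by sweeping the
#' canonical rotamer library on the fixed native backbone and measuring, for
#' each rotamer, the worst hard-sphere overlap `(r_i + r_j) - d` of the
#' built side-chain atoms against all environment heavy atoms (both binding
#' partners; the replaced side chain, the mutated residue's own backbone and
#' the directly bonded peptide atoms of its sequence neighbours are
#' excluded).  A rotamer is clash-free when its worst overlap does not exceed
#' `overlapCutoff`.
#'
#' @param model a [Structure-class] (alternate locations should be resolved).
#' @param chain chain of the mutated residue.
#' @param position author residue number.
#' @param newResidue three-letter code of the substitution.
#' @param rotamers rotamer library, as from [defaultRotamerLibrary()].
#' @param overlapCutoff tolerated overlap in Angstrom (0.4, the common
#'   steric-clash convention).
#' @param radii a [RadiusSet-class].
#' @param insert insertion code of the mutated residue.
#' @return a [ClashReport-class].
#' @export
mutateAndScan <- function(model, chain, position, newResidue,
                          rotamers = defaultRotamerLibrary(),
                          overlapCutoff = 0.4, radii = defaultRadiusSet(),
                          insert = "") {
  stopifnot(is(model, "Structure"))
  newResidue <- toupper(newResidue)
  if (!newResidue %in% names(rotamers))
    stop("unsupported residue type: ", newResidue)
  a <- .proteinHeavyAtoms(model)
  own <- a$chainId == chain & a$resSeq == position & a$insert == insert
  if (!any(own))
    stop("residue ", position, " of chain ", chain,
         " is not modeled in the structure")
  backbone <- list()
  for (at in c("N", "CA", "C", "CB")) {
    i <- which(own & a$name == at)
    if (length(i) == 1) backbone[[at]] <- c(a$x[i], a$y[i], a$z[i])
  }
  if (is.null(backbone$N) || is.null(backbone$CA) || is.null(backbone$C))
    stop("backbone atoms N/CA/C incomplete for residue ", position,
         " of chain ", chain)
  # environment: everything except the mutated residue itself and the peptide
  # atoms bonded to it (<= 3 bonds from the new C-beta)
  adjacent <- (a$chainId == chain & a$resSeq == position - 1 & a$name == "C") |
              (a$chainId == chain & a$resSeq == position + 1 & a$name == "N")
  env <- a[!own & !adjacent, , drop = FALSE]
  envXyz <- as.matrix(env[, c("x", "y", "z")])
  envR <- if (nrow(env) > 0) atomRadii(env, radii) else numeric(0)
  lib <- rotamers[[newResidue]]
  nRot <- nrow(lib)
  overlaps <- rep(-Inf, nRot)
  for (r in seq_len(nRot)) {
    side <- buildSideChain(newResidue, backbone, as.numeric(lib[r, ]))
    if (length(side) == 0 || nrow(env) == 0) next  # glycine: nothing to clash
    sideAtoms <- data.frame(resName = newResidue, name = names(side),
                            element = substr(sub("^[0-9']+", "",
                                                 names(side)), 1, 1),
                            chainId = chain, resSeq = position,
                            stringsAsFactors = FALSE)
    sideXyz <- do.call(rbind, side)
    overlaps[r] <- .worstOverlap(sideXyz, atomRadii(sideAtoms, radii),
                                 envXyz, envR)
  }
  new("ClashReport", chainId = chain, position = as.integer(position),
      insert = insert, newResidue = newResidue, rotamerOverlaps = overlaps,
      clashFreeFraction = mean(overlaps <= overlapCutoff),
      overlapCutoff = overlapCutoff)
}

#' Rule-based Spo0F-phosphatase verdict for a candidate Rap protein
#'
#' Combines the three evidence axes into a deterministic call:
#' * phosphatase -- catalytic Gln/Glu present, identity fraction at the
#'   conserved interfacial positions at or above `identityThreshold`, and no
#'   mismatch position whose every rotamer clashes;
#' * non-phosphatase -- the catalytic check fails, or identity falls below
#'   the threshold, or some mismatched substitution is fully clash-blocked;
#' * indeterminate -- the sequence rules pass but no structure was available
#'   to clash-scan the mismatches.
#'
#' @param score a [CandidateScore-class].
#' @param catalytic result of [catalyticCheck()].
#' @param clashReports list of [ClashReport-class] for the mismatch
#'   positions, or `NULL` when no structure is available.
#' @param identityThreshold minimal identity fraction (default 12/18, between
#'   the observed non-phosphatase and phosphatase extremes).
#' @return a [SpecificityVerdict-class] with all evidence attached.
#' @export
predictPhosphatase <- function(score, catalytic, clashReports = NULL,
                               identityThreshold = 12 / 18) {
  stopifnot(is(score, "CandidateScore"))
  frac <- if (score@nTotal > 0) score@nMatch / score@nTotal else 0
  blocked <- integer(0)
  clashKnown <- !is.null(clashReports)
  if (clashKnown && length(clashReports) > 0) {
    zero <- vapply(clashReports, function(cr) cr@clashFreeFraction == 0,
                   logical(1))
    blocked <- sort(vapply(clashReports[zero], function(cr) cr@position,
                           integer(1)))
  }
  call <- if (!catalytic$pass || frac < identityThreshold ||
              length(blocked) > 0) {
    "non-phosphatase"
  } else if (!clashKnown && nrow(score@mismatches) > 0) {
    "indeterminate"
  } else {
    "phosphatase"
  }
  new("SpecificityVerdict", candidateId = score@candidateId, call = call,
      identityFraction = frac, nMatch = score@nMatch, nTotal = score@nTotal,
      catalyticPass = catalytic$pass, catalyticResidue = catalytic$residue,
      blockedPositions = blocked, mismatches = score@mismatches,
      thresholds = list(identityThreshold = identityThreshold,
                        catalyticPosition = catalytic$position))
}
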