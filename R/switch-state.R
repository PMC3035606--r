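#' Receiver-domain switch residue configuration
#'
#' Residue numbers and thresholds for the switch-state classifier, with
#' Spo0F defaults (Thr82 hydroxyl switch, His101 aromatic-position switch,
#' Asp54 phosphoacceptor, beta4-alpha4 loop window 82-85).  Supplying a
#' different mapping generalises the classifier to other CheY-like receiver
#' domains.
#'
#' @param thrRes hydroxyl switch residue number.
#' @param aspRes active-site aspartate residue number.
#' @param hisRes aromatic/imidazole switch residue number.
#' @param loopStart first residue of the four-C-alpha loop window.
#' @param distanceCutoff Thr O-gamma to Asp C-gamma distance (Angstrom) at or
#'   below which the hydroxyl switch counts as rotated toward the active
#'   site.
#' @param relSasaCutoff relative side-chain SASA at or below which the
#'   aromatic switch counts as internalized.
#' @return a named list.
#' @export
receiverConfig <- function(thrRes = 82L, aspRes = 54L, hisRes = 101L,
                           loopStart = 82L, distanceCutoff = 5.5,
                           relSasaCutoff = 0.15) {
  list(thrRes = as.integer(thrRes), aspRes = as.integer(aspRes),
       hisRes = as.integer(hisRes), loopStart = as.integer(loopStart),
       distanceCutoff = distanceCutoff, relSasaCutoff = relSasaCutoff)
}

#' Hydroxyl-switch orientation
#'
#' Operationalises "rotated toward the active site" as a distance test: the
#' switch threonine/serine O-gamma lies within `cutoff` of the
#' phosphoacceptor aspartate C-gamma.
#'
#' @param model a [Structure-class].
#' @param chain receiver chain.
#' @param thrRes,aspRes residue numbers of the switch Thr/Ser and acceptor
#'   Asp.
#' @param cutoff distance cutoff, Angstrom.
#' @return `"toward"`, `"away"`, or `"indeterminate"` when the side-chain
#'   atoms are not modeled.
#' @export
thrSwitchOrientation <- function(model, chain, thrRes = 82L, aspRes = 54L,
                                 cutoff = 5.5) {
  a <- .proteinHeavyAtoms(model)
  og <- which(a$chainId == chain & a$resSeq == thrRes &
              a$name %in% c("OG1", "OG"))
  cg <- which(a$chainId == chain & a$resSeq == aspRes & a$name == "CG")
  if (length(og) == 0 || length(cg) == 0) return("indeterminate")
  og <- og[1]; cg <- cg[1]
  d <- sqrt((a$x[og] - a$x[cg])^2 + (a$y[og] - a$y[cg])^2 +
            (a$z[og] - a$z[cg])^2)
  if (d <= cutoff) "toward" else "away"
}

#' Aromatic-switch burial state
#'
#' The switch histidine counts as internal when the solvent-accessible area
#' of its side chain, relative to the same side chain in an extended
#' Gly-His-Gly reference peptide, falls at or below `relSasaCutoff`.
#'
#' @param model a [Structure-class].
#' @param chain receiver chain.
#' @param hisRes switch residue number.
#' @param relSasaCutoff relative accessibility cutoff.
#' @param radii,probe,nPoints SASA parameters (see [shrakeRupleySasa()]).
#' @return `"internal"`, `"external"`, or `"indeterminate"` when the side
#'   chain is not modeled.
#' @export
hisBurialState <- function(model, chain, hisRes = 101L, relSasaCutoff = 0.15,
                           radii = defaultRadiusSet(), probe = 1.4,
                           nPoints = 960L) {
  a <- .proteinHeavyAtoms(model)
  own <- a$chainId == chain & a$resSeq == hisRes
  sideNames <- setdiff(a$name[own], c("N", "CA", "C", "O"))
  if (length(sideNames) < 2) return("indeterminate")
  resName <- a$resName[own][1]
  sasa <- shrakeRupleySasa(model, radii, probe, nPoints)
  sel <- sasa@atoms$chainId == chain & sasa@atoms$resSeq == hisRes &
    !(sasa@atoms$name %in% c("N", "CA", "C", "O"))
  area <- sum(sasa@atomArea[sel])
  ref <- referenceSideChainArea(resName, radii, probe, nPoints)
  if (area / ref <= relSasaCutoff) "internal" else "external"
}

#' Classify a receiver-domain copy by its switch observables
#'
#' Combines the hydroxyl-switch orientation, the aromatic-switch burial and
#' the beta4-alpha4 loop pseudodihedral into a single report.  The overall
#' label is `"phosphorylated-like"` when the Thr switch points toward the
#' active site and the His switch is internal, `"non-phosphorylated-like"`
#' when the Thr switch points away and the His switch is external, and
#' `"mixed"` otherwise (indeterminate axes propagate to `"mixed"`).  The
#' loop angle is reported as observed -- `NA` when the loop is disordered --
#' and never enforced on the label.
#'
#' @param model a [Structure-class].
#' @param chain receiver chain.
#' @param config a [receiverConfig()] list.
#' @param radii,probe,nPoints SASA parameters for the burial axis.
#' @return a [SwitchStateReport-class].
#' @export
classifyReceiverState <- function(model, chain, config = receiverConfig(),
                                  radii = defaultRadiusSet(), probe = 1.4,
                                  nPoints = 960L) {
  thr <- thrSwitchOrientation(model, chain, config$thrRes, config$aspRes,
                              config$distanceCutoff)
  his <- hisBurialState(model, chain, config$hisRes, config$relSasaCutoff,
                        radii, probe, nPoints)
  loop <- pseudodihedralCa(model, chain, config$loopStart)
  overall <- if (thr == "toward" && his == "internal") {
    "phosphorylated-like"
  } else if (thr == "away" && his == "external") {
    "non-phosphorylated-like"
  } else {
    "mixed"
  }
  new("SwitchStateReport", chainId = chain, thrOrientation = thr,
      hisEnvironment = his, loopAngle = loop, overall = overall)
}
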