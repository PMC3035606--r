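.AA1TO3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
             G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
             M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
             S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

#' Assemble a pipeline configuration
#'
#' Flat key-value configuration consumed by [runStructureReport()] and
#' [runSpecificityPipeline()].  Every threshold the pipeline uses is carried
#' here and serialized into every report, so a report is fully reproducible
#' from its own embedded configuration.
#'
#' @param pdb path to the structure file (PDB format), or `NULL` for
#'   sequence-only runs.
#' @param msa path to the aligned FASTA, or `NULL` for structure-only runs.
#' @param groupA,groupB chain-group specifications for the interface of
#'   interest, e.g. `"A"` or `c("A:277-376")` (see [chainGroup()]).
#' @param receiverChains chains classified by [classifyReceiverState()].
#' @param superpose list of `c(mobile, reference)` chain pairs to superpose.
#' @param referenceId reference (structure-numbered) sequence id of the MSA.
#' @param trainingIds ids of the demonstrated phosphatases.
#' @param candidateIds ids to score and call.
#' @param scanChain structure chain used for rotamer clash scans of candidate
#'   mismatches; `NULL` disables clash scanning (verdicts may then be
#'   indeterminate).
#' @param deltaSasaThreshold per-residue buried-area threshold, Angstrom^2.
#' @param conservationThreshold column conservation threshold.
#' @param identityThreshold verdict identity-fraction threshold.
#' @param overlapCutoff rotamer hard-sphere overlap tolerance, Angstrom.
#' @param catalyticPosition reference-numbered catalytic Gln/Glu position.
#' @param thrRes,aspRes,hisRes,loopStart,distanceCutoff,relSasaCutoff
#'   receiver-switch settings (see [receiverConfig()]).
#' @param probe probe radius, Angstrom.
#' @param nPoints sphere points per atom.
#' @param seed integer recorded in reports (the pipeline itself is
#'   deterministic; the seed feeds fixture generation in `simulate` runs).
#' @return a named list of class `rapspecConfig`.
#' @export
pipelineConfig <- function(pdb = NULL, msa = NULL,
                           groupA = "A", groupB = "B",
                           receiverChains = character(0),
                           superpose = list(),
                           referenceId = NULL,
                           trainingIds = character(0),
                           candidateIds = character(0),
                           scanChain = NULL,
                           deltaSasaThreshold = 1.0,
                           conservationThreshold = 5 / 6,
                           identityThreshold = 12 / 18,
                           overlapCutoff = 0.4,
                           catalyticPosition = 47L,
                           thrRes = 82L, aspRes = 54L, hisRes = 101L,
                           loopStart = 82L,
                           distanceCutoff = 5.5, relSasaCutoff = 0.15,
                           probe = 1.4, nPoints = 960L, seed = 1L) {
  config <- list(pdb = pdb, msa = msa, groupA = groupA, groupB = groupB,
                 receiverChains = receiverChains, superpose = superpose,
                 referenceId = referenceId, trainingIds = trainingIds,
                 candidateIds = candidateIds, scanChain = scanChain,
                 deltaSasaThreshold = deltaSasaThreshold,
                 conservationThreshold = conservationThreshold,
                 identityThreshold = identityThreshold,
                 overlapCutoff = overlapCutoff,
                 catalyticPosition = as.integer(catalyticPosition),
                 thrRes = as.integer(thrRes), aspRes = as.integer(aspRes),
                 hisRes = as.integer(hisRes),
                 loopStart = as.integer(loopStart),
                 distanceCutoff = distanceCutoff,
                 relSasaCutoff = relSasaCutoff,
                 probe = probe, nPoints = as.integer(nPoints),
                 seed = as.integer(seed))
  class(config) <- "rapspecConfig"
  config
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are an error (they are always a typo of a real threshold).
#'
#' @param file path to a YAML file of [pipelineConfig()] keys.
#' @return a `rapspecConfig` list.
#' @export
readPipelineConfig <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  values <- yaml::read_yaml(file)
  if (is.null(values)) values <- list()
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(values), known)
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, values)
}

.asConfig <- function(config) {
  if (inherits(config, "rapspecConfig")) return(config)
  do.call(pipelineConfig, config)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[rapspec] stage %-14s %6.2f s", name,
                  proc.time()[["elapsed"]] - t0))
  result
}

.loadStructure <- function(config) {
  model <- readPDB(config$pdb)
  resolveAltLocs(model)
}

.switchReportList <- function(report) {
  list(chain = report@chainId, thrOrientation = report@thrOrientation,
       hisEnvironment = report@hisEnvironment,
       loopAngle = if (is.na(report@loopAngle)) "disordered"
                   else report@loopAngle,
       overall = report@overall)
}

#' Run the structural half of the analysis
#'
#' Structure to interface quantification, chain superpositions and
#' receiver-domain switch states, in one machine-readable bundle.
#'
#' @param config a [pipelineConfig()] list (or a plain list of its keys).
#' @return a list with elements `interface`, `superpositions`,
#'   `switchStates`, plus the resolved `config` and package `version`.
#'   Re-running this function on the embedded `config` reproduces the report
#'   bit-identically.
#' @export
runStructureReport <- function(config) {
  config <- .asConfig(config)
  if (is.null(config$pdb)) stop("stage 'input' failed: no structure input",
                                call. = FALSE)
  model <- .stage("read", .loadStructure(config))

  interface <- .stage("interface", {
    ir <- interfaceResidues(model, chainGroup(config$groupA, "A"),
                            chainGroup(config$groupB, "B"),
                            threshold = config$deltaSasaThreshold,
                            probe = config$probe, nPoints = config$nPoints)
    list(groupA = config$groupA, groupB = config$groupB,
         totalBsa = ir@totalBsa,
         residuesA = interfaceSide(ir, "A"), residuesB = interfaceSide(ir, "B"))
  })

  superpositions <- .stage("superpose", lapply(config$superpose, function(p) {
    map <- buildCorrespondence(model, model, p[[1]], p[[2]])
    sup <- superposeChains(model, model, map)
    list(mobile = p[[1]], reference = p[[2]], rmsd = sup@rmsd,
         nPairs = sup@nPairs)
  }))

  receiver <- receiverConfig(config$thrRes, config$aspRes, config$hisRes,
                             config$loopStart, config$distanceCutoff,
                             config$relSasaCutoff)
  switchStates <- .stage("switch", lapply(config$receiverChains, function(ch)
    .switchReportList(classifyReceiverState(model, ch, receiver,
                                            probe = config$probe,
                                            nPoints = config$nPoints))))

  list(report = "structure", interface = interface,
       superpositions = superpositions, switchStates = switchStates,
       config = unclass(config),
       version = as.character(utils::packageVersion("rapspec")))
}

#' Run the end-to-end specificity analysis
#'
#' Interface quantification, conservation mapping, candidate scoring, rotamer
#' clash scanning of the mismatches and the final phosphatase verdicts, in
#' one machine-readable bundle.  The run completes (and a CLI wrapper should
#' exit zero) whatever the verdicts are; only stage failures are errors.
#'
#' @param config a [pipelineConfig()] list (or a plain list of its keys).
#' @return a list with elements `conservedPositions` and one evidence bundle
#'   per candidate (`score`, `catalytic`, `clashScan`, `verdict`), plus the
#'   resolved `config` and package `version`.
#' @export
runSpecificityPipeline <- function(config) {
  config <- .asConfig(config)
  if (is.null(config$pdb) || is.null(config$msa) ||
      is.null(config$referenceId))
    stop("stage 'input' failed: need pdb, msa and referenceId", call. = FALSE)
  model <- .stage("read", .loadStructure(config))
  profile <- .stage("msa", readMsa(config$msa, config$referenceId))

  interface <- .stage("interface",
    interfaceResidues(model, chainGroup(config$groupA, "A"),
                      chainGroup(config$groupB, "B"),
                      threshold = config$deltaSasaThreshold,
                      probe = config$probe, nPoints = config$nPoints))

  positions <- .stage("conservation", {
    scores <- columnConservation(profile, config$trainingIds)
    conservedInterfacePositions(scores, interface,
                                threshold = config$conservationThreshold,
                                trainingIds = config$trainingIds)
  })

  candidates <- .stage("verdict", lapply(config$candidateIds, function(id) {
    score <- scoreCandidate(id, profile, positions, config$trainingIds)
    catalytic <- catalyticCheck(id, profile, config$catalyticPosition)
    clashReports <- NULL
    if (!is.null(config$scanChain) && nrow(score@mismatches) > 0) {
      clashReports <- lapply(seq_len(nrow(score@mismatches)), function(k) {
        res1 <- score@mismatches$candidate[k]
        if (!res1 %in% names(.AA1TO3)) return(NULL)  # gap: nothing to build
        mutateAndScan(model, config$scanChain, score@mismatches$position[k],
                      .AA1TO3[[res1]], overlapCutoff = config$overlapCutoff)
      })
      clashReports <- Filter(Negate(is.null), clashReports)
    } else if (!is.null(config$scanChain)) {
      clashReports <- list()
    }
    verdict <- predictPhosphatase(score, catalytic, clashReports,
                                  config$identityThreshold)
    list(candidate = id, call = verdict@call,
         nMatch = verdict@nMatch, nTotal = verdict@nTotal,
         identityFraction = verdict@identityFraction,
         catalyticPass = verdict@catalyticPass,
         catalyticResidue = verdict@catalyticResidue,
         blockedPositions = verdict@blockedPositions,
         mismatchPositions = score@mismatches$position,
         clashFreeFractions = if (is.null(clashReports)) NULL else
           vapply(clashReports, function(cr) cr@clashFreeFraction, numeric(1)))
  }))

  list(report = "specificity",
       conservedPositions = positions@positions,
       conservationScores = as.numeric(positions@scores),
       candidates = candidates,
       config = unclass(config),
       version = as.character(utils::packageVersion("rapspec")))
}

#' Write a pipeline report as JSON
#'
#' @param report a bundle from [runStructureReport()] or
#'   [runSpecificityPipeline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReportJSON <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
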