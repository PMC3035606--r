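#' Read an aligned FASTA file into an MSA profile
#'
#' Consumes an already-aligned FASTA (alignment itself is an upstream input,
#' not a computation performed here) and builds the column/reference-position
#' bookkeeping.  Ragged alignments and a missing reference id are errors.
#'
#' @param file path to an aligned FASTA file.
#' @param referenceId identifier of the reference sequence whose ungapped
#'   numbering (RapH numbering in the study system) labels the columns.
#' @return an [MsaProfile-class].
#' @export
readMsa <- function(file, referenceId) {
  seqs <- Biostrings::readAAStringSet(file)
  v <- as.character(seqs)
  names(v) <- sub("\\s.*$", "", names(seqs))
  msaProfile(v, referenceId)
}

#' Build an MSA profile from named aligned strings
#'
#' @param sequences named character vector of equal-length aligned sequences
#'   (gap character `"-"`; `"."` is normalised to `"-"`).
#' @param referenceId name of the reference sequence.
#' @return an [MsaProfile-class].
#' @export
msaProfile <- function(sequences, referenceId) {
  if (length(sequences) < 2) stop("need at least 2 sequences")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named")
  w <- nchar(sequences)
  if (length(unique(w)) != 1)
    stop("ragged alignment: sequence lengths ",
         paste(unique(w), collapse = ", "))
  if (!referenceId %in% names(sequences))
    stop("reference id '", referenceId, "' not in alignment; ids: ",
         paste(names(sequences), collapse = ", "))
  aln <- do.call(rbind, strsplit(toupper(sequences), ""))
  aln[aln == "."] <- "-"
  rownames(aln) <- names(sequences)
  refRow <- aln[referenceId, ]
  refMap <- rep(NA_integer_, ncol(aln))
  refMap[refRow != "-"] <- seq_len(sum(refRow != "-"))
  new("MsaProfile", ids = names(sequences), aln = aln,
      referenceId = referenceId, referenceMap = refMap)
}

.columnOf <- function(profile, refPos) {
  col <- match(refPos, profile@referenceMap)
  if (any(is.na(col)))
    stop("reference position(s) ", paste(refPos[is.na(col)], collapse = ", "),
         " do not map to an alignment column")
  col
}

#' Per-column conservation over a training set
#'
#' Transparent frequency score: for each alignment column the score is the
#' frequency of the modal residue among the training sequences (identity
#' classes; gaps never count as a match), so a fully identical column scores
#' 1 and a 5-of-6 column scores 0.833.  This replaces phylogeny-weighted
#' conservation scoring with a single interpretable parameter.
#'
#' @param profile an [MsaProfile-class].
#' @param trainingIds sequence ids of the proteins demonstrated to
#'   dephosphorylate the target (the calibration set).
#' @return `data.frame` with columns `column`, `refPos`, `score`.
#' @export
columnConservation <- function(profile, trainingIds) {
  stopifnot(is(profile, "MsaProfile"))
  if (length(trainingIds) == 0) stop("empty training set")
  missing <- setdiff(trainingIds, profile@ids)
  if (length(missing) > 0)
    stop("training id(s) not in alignment: ", paste(missing, collapse = ", "))
  sub <- profile@aln[trainingIds, , drop = FALSE]
  n <- length(trainingIds)
  score <- apply(sub, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(0)
    max(table(col)) / n
  })
  data.frame(column = seq_len(ncol(profile@aln)),
             refPos = profile@referenceMap,
             score = as.numeric(score))
}

#' Conserved positions lying in the structural interface
#'
#' Intersects the conservation scores with the interface residue set of the
#' Rap side of the complex: a position qualifies when its conservation score
#' reaches `threshold` and its reference residue number is buried in the
#' interface.  Columns where the reference sequence has a gap can never be
#' interface positions.
#'
#' @param scores output of [columnConservation()].
#' @param interfacePositions integer vector of reference residue numbers in
#'   the interface (e.g. `interfaceSide(report, "A")`), or an
#'   [InterfaceReport-class] whose A side is the reference protein.
#' @param threshold conservation threshold; the default 5/6 requires all
#'   training phosphatases but at most one to agree.
#' @param trainingIds recorded in the result for provenance.
#' @return a [ConservedPositionSet-class].
#' @export
conservedInterfacePositions <- function(scores, interfacePositions,
                                        threshold = 5 / 6,
                                        trainingIds = character(0)) {
  if (is(interfacePositions, "InterfaceReport"))
    interfacePositions <- interfaceSide(interfacePositions, "A")
  ok <- !is.na(scores$refPos) & scores$score >= threshold &
    scores$refPos %in% interfacePositions
  pos <- sort(as.integer(scores$refPos[ok]))
  sc <- scores$score[ok][order(scores$refPos[ok])]
  names(sc) <- pos
  new("ConservedPositionSet", positions = pos, scores = sc,
      threshold = threshold, trainingIds = as.character(trainingIds))
}

#' Apply a point substitution to one sequence of an alignment
#'
#' Used to test engineered variants (e.g. RapF-H50L) through the same
#' scoring machinery as wild-type sequences.
#'
#' @param profile an [MsaProfile-class].
#' @param id sequence to modify.
#' @param refPos reference-numbered position of the substitution.
#' @param newResidue one-letter code.
#' @return a modified [MsaProfile-class].
#' @export
substituteResidue <- function(profile, id, refPos, newResidue) {
  stopifnot(is(profile, "MsaProfile"))
  if (!id %in% profile@ids) stop("no sequence named ", id)
  col <- .columnOf(profile, refPos)
  aln <- profile@aln
  aln[id, col] <- toupper(newResidue)
  new("MsaProfile", ids = profile@ids, aln = aln,
      referenceId = profile@referenceId, referenceMap = profile@referenceMap)
}
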