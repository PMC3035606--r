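#' Read a protein structure from a PDB file
#'
#' Parses the fixed-column PDB v3 dialect (`ATOM`/`HETATM`/`TER`/`END`
#' records) into a [Structure-class].  Author residue numbering and insertion
#' codes are preserved verbatim; if the file contains several `MODEL` blocks
#' only the first is kept.  Record parsing is delegated to
#' `bio3d::read.pdb()` after a light fixed-width validation pass so that a
#' malformed line is reported with its line number.
#'
#' @param file path to a PDB file.
#' @return a [Structure-class] (alternate locations unresolved; see
#'   [resolveAltLocs()]).
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeLines(paste0("ATOM      1  CA  GLY A   1      ",
#'                   "11.104  13.207   2.100  1.00 20.00           C"), f)
#' readPDB(f)
#' @export
readPDB <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  lines <- readLines(file, warn = FALSE)
  .validatePdbLines(lines)
  pdb <- suppressWarnings(bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  a <- pdb$atom
  title <- sub("^TITLE\\s+\\d*\\s*", "", grep("^TITLE", lines, value = TRUE))
  title <- if (length(title) > 0) trimws(paste(title, collapse = " ")) else ""
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    altLoc = ifelse(is.na(a$alt), "", a$alt),
    resName = trimws(a$resid),
    chainId = ifelse(is.na(a$chain), "", a$chain),
    resSeq = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    bFactor = ifelse(is.na(a$b), 0, a$b),
    element = .deriveElement(a$elesy, a$elety, a$resid),
    isHetero = a$type == "HETATM",
    stringsAsFactors = FALSE)
  new("Structure", atoms = atoms, title = title, resolvedAltLocs = FALSE)
}

#' Parse PDB-format text
#'
#' Convenience wrapper around [readPDB()] for in-memory PDB text (for example
#' output of the synthetic fixture generators).
#'
#' @param text character vector of PDB lines, or a single string with
#'   embedded newlines.
#' @return a [Structure-class].
#' @export
parsePDBText <- function(text) {
  if (length(text) == 1) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeLines(text, f)
  readPDB(f)
}

.validatePdbLines <- function(lines) {
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(sel) == 0)
    stop("empty input: no ATOM/HETATM records found")
  for (i in sel) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed fixed-width PDB line ", i, ": shorter than 54 columns")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed fixed-width PDB line ", i, ": non-numeric coordinates")
  }
  invisible(TRUE)
}

.TWO_LETTER_ELEMENTS <- c("MG", "MN", "FE", "ZN", "CL", "BR", "SE", "NI",
                          "CU", "CO", "CD", "NA", "K")

.deriveElement <- function(elesy, elety, resid) {
  out <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- !nzchar(out)
  if (any(miss)) {
    nm <- toupper(trimws(elety[miss]))
    rs <- toupper(trimws(resid[miss]))
    # hetero ions are commonly named after their element
    ion <- nm == rs & nm %in% .TWO_LETTER_ELEMENTS
    stripped <- sub("^[0-9']+", "", nm)
    first <- substr(stripped, 1, 1)
    out[miss] <- ifelse(ion, nm, first)
  }
  out
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column `ATOM`/`HETATM` records (via `bio3d::write.pdb()`) so
#' that `readPDB(writePDB(x))` round-trips atom count, names, residue
#' identifiers and coordinates at PDB precision (3 decimals).
#'
#' @param model a [Structure-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writePDB <- function(model, file) {
  stopifnot(is(model, "Structure"))
  a <- model@atoms
  if (nrow(a) == 0) stop("refusing to write a structure with no atoms")
  bio3d::write.pdb(pdb = NULL, file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$isHetero, "HETATM", "ATOM"),
                   resno = a$resSeq,
                   resid = a$resName,
                   eleno = a$serial,
                   elety = a$name,
                   chain = ifelse(nzchar(a$chainId), a$chainId, NA),
                   insert = ifelse(nzchar(a$insert), a$insert, NA),
                   alt = ifelse(nzchar(a$altLoc), a$altLoc, NA),
                   o = a$occupancy,
                   b = a$bFactor,
                   elesy = a$element)
  invisible(file)
}

#' Resolve alternate atom locations
#'
#' For every alternate-location group (same chain, residue, insertion code
#' and atom name) only the highest-occupancy conformer is retained; ties are
#' broken in favour of the alphabetically first altLoc identifier.  The
#' operation is idempotent.
#'
#' @param model a [Structure-class].
#' @return a [Structure-class] with `resolvedAltLocs = TRUE`.
#' @export
resolveAltLocs <- function(model) {
  stopifnot(is(model, "Structure"))
  a <- model@atoms
  if (nrow(a) > 0) {
    key <- paste(a$chainId, a$resSeq, a$insert, a$name, sep = "\r")
    # order so the preferred conformer comes first within each group:
    # highest occupancy, then alphabetical altLoc
    ord <- order(key, -a$occupancy, a$altLoc)
    a <- a[ord, , drop = FALSE]
    keep <- !duplicated(key[ord])
    a <- a[keep, , drop = FALSE]
    a <- a[order(match(a$serial, model@atoms$serial)), , drop = FALSE]
    a$altLoc <- ""
    rownames(a) <- NULL
  }
  new("Structure", atoms = a, title = model@title, resolvedAltLocs = TRUE)
}

#' Define a chain group
#'
#' @param spec character vector of selections, each either a bare chain id
#'   (`"A"`) or a chain with an author-numbering residue range
#'   (`"B:1-76"`).
#' @param label optional group label; defaults to the collapsed spec.
#' @return a [ChainGroup-class].
#' @examples
#' chainGroup("A", label = "RapH_A")
#' chainGroup("A:1-76", label = "RapH_A 3-helix bundle")
#' @export
chainGroup <- function(spec, label = paste(spec, collapse = "+")) {
  chains <- character(length(spec))
  ranges <- vector("list", length(spec))
  for (i in seq_along(spec)) {
    parts <- strsplit(spec[i], ":", fixed = TRUE)[[1]]
    chains[i] <- parts[1]
    if (length(parts) == 2) {
      se <- suppressWarnings(as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]]))
      if (length(se) != 2 || any(is.na(se)) || se[1] > se[2])
        stop("cannot parse residue range in group spec: ", spec[i])
      ranges[[i]] <- se[1]:se[2]
    } else if (length(parts) != 1) {
      stop("cannot parse group spec: ", spec[i])
    }
  }
  names(ranges) <- chains
  new("ChainGroup", label = label, chains = chains, ranges = ranges)
}

#' Select part of a structure
#'
#' Projects a [Structure-class] onto the chains/residue ranges of a
#' [ChainGroup-class].  Selecting is a projection:
#' `selectAtoms(selectAtoms(m, g), g)` equals `selectAtoms(m, g)`.
#'
#' @param model a [Structure-class].
#' @param group a [ChainGroup-class] (or a spec string accepted by
#'   [chainGroup()]).
#' @param heavyOnly drop hydrogen/deuterium atoms.
#' @return a [Structure-class] containing the matching atoms.
#' @export
selectAtoms <- function(model, group, heavyOnly = FALSE) {
  stopifnot(is(model, "Structure"))
  if (is.character(group)) group <- chainGroup(group)
  a <- model@atoms
  unknown <- setdiff(group@chains, unique(a$chainId))
  if (length(unknown) > 0)
    stop("unknown chain id(s) ", paste(unknown, collapse = ", "),
         "; available chains: ",
         paste(unique(a$chainId), collapse = ", "))
  keep <- rep(FALSE, nrow(a))
  for (i in seq_along(group@chains)) {
    sel <- a$chainId == group@chains[i]
    r <- group@ranges[[i]]
    if (!is.null(r)) sel <- sel & a$resSeq %in% r
    keep <- keep | sel
  }
  if (heavyOnly) keep <- keep & !(a$element %in% c("H", "D"))
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("Structure", atoms = out, title = model@title,
      resolvedAltLocs = model@resolvedAltLocs)
}

# heavy, non-water, non-hetero atom table used by SASA/clash computations
.proteinHeavyAtoms <- function(model, includeHetero = FALSE) {
  a <- model@atoms
  keep <- !(a$element %in% c("H", "D")) & !(a$resName %in% c("HOH", "WAT", "DOD"))
  if (!includeHetero) keep <- keep & !a$isHetero
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.structureFromAtoms <- function(atoms, title = "", resolved = TRUE) {
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms, title = title, resolvedAltLocs = resolved)
}
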