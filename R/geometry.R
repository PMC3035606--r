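.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed torsion angle of four points
#'
#' Standard signed dihedral about the p2->p3 axis, in degrees on the interval
#' (-180, 180].  The cis arrangement gives 0 and trans gives 180.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees.
#' @examples
#' dihedralAngle(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0), c(1, -1, 0)) # trans: 180
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n2 <- sqrt(sum(b2^2))
  if (sqrt(sum(b1^2)) < 1e-9 || n2 < 1e-9 || sqrt(sum(b3^2)) < 1e-9)
    stop("degenerate geometry: coincident consecutive points")
  c1 <- .cross3(b1, b2)
  c2 <- .cross3(b2, b3)
  if (sum(c1^2) < 1e-18 || sum(c2^2) < 1e-18)
    stop("degenerate geometry: collinear points leave the torsion undefined")
  x <- sum(c1 * c2)
  y <- sum(.cross3(c1, c2) * (b2 / n2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone pseudodihedral over four consecutive C-alpha atoms
#'
#' The four-C-alpha pseudodihedral of residues `startRes .. startRes + 3`,
#' the metric used to quantify beta4-alpha4 loop rotation in receiver
#' domains (Spo0F residues 82-85 by default in this package's switch-state
#' classifier).  A missing C-alpha -- a disordered loop -- yields `NA`, the
#' "disordered" signal, rather than a number.
#'
#' @param model a [Structure-class].
#' @param chain chain identifier.
#' @param startRes first residue number of the quadruple.
#' @return angle in degrees, or `NA_real_` when any C-alpha is unmodeled.
#' @export
pseudodihedralCa <- function(model, chain, startRes) {
  stopifnot(is(model, "Structure"))
  a <- model@atoms
  pts <- lapply(startRes + 0:3, function(r) {
    i <- which(a$chainId == chain & a$resSeq == r & a$name == "CA" &
               !a$isHetero)
    if (length(i) == 0) return(NULL)
    c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
  })
  if (any(vapply(pts, is.null, logical(1)))) return(NA_real_)
  dihedralAngle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}

#' Minimal angular difference on the circle
#'
#' @param a,b angles in degrees.
#' @return absolute difference in `[0, 180]`.
#' @export
angularDifference <- function(a, b) {
  d <- abs(a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Build a residue correspondence between two chains of the same protein
#'
#' Pairs residues of a mobile and a reference chain either by shared author
#' numbering (the default, appropriate for two crystallographic copies of the
#' same protein) or from an explicit residue-pair table for heterologous
#' proteins.  Only residues carrying the pairing atom (`CA` by default) on
#' both sides are kept.
#'
#' @param mobile,reference [Structure-class] objects (may be the same).
#' @param mobileChain,refChain chain identifiers.
#' @param pairs optional `data.frame` with columns `mobileRes`, `refRes`
#'   giving an explicit pairing; when `NULL`, identical author numbering is
#'   used.
#' @param atomName atom used for pairing.
#' @return a [CorrespondenceMap-class].
#' @export
buildCorrespondence <- function(mobile, reference, mobileChain, refChain,
                                pairs = NULL, atomName = "CA") {
  stopifnot(is(mobile, "Structure"), is(reference, "Structure"))
  present <- function(model, chain) {
    a <- model@atoms
    sort(unique(a$resSeq[a$chainId == chain & a$name == atomName &
                         !a$isHetero]))
  }
  mres <- present(mobile, mobileChain)
  rres <- present(reference, refChain)
  if (is.null(pairs)) {
    shared <- intersect(mres, rres)
    pairs <- data.frame(mobileRes = shared, refRes = shared)
  } else {
    keep <- pairs$mobileRes %in% mres & pairs$refRes %in% rres
    pairs <- pairs[keep, c("mobileRes", "refRes"), drop = FALSE]
  }
  if (nrow(pairs) < 3)
    stop("fewer than 3 residue pairs with ", atomName,
         " modeled on both sides")
  rownames(pairs) <- NULL
  new("CorrespondenceMap", pairs = pairs, mobileChain = mobileChain,
      refChain = refChain, atomName = atomName)
}

.pairedCoords <- function(model, chain, residues, atomName) {
  a <- model@atoms
  out <- matrix(NA_real_, nrow = length(residues), ncol = 3)
  for (k in seq_along(residues)) {
    i <- which(a$chainId == chain & a$resSeq == residues[k] &
               a$name == atomName & !a$isHetero)
    if (length(i) == 0)
      stop("atom ", atomName, " missing for residue ", residues[k],
           " in chain ", chain)
    out[k, ] <- c(a$x[i[1]], a$y[i[1]], a$z[i[1]])
  }
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets, by singular value decomposition of the covariance
#' matrix with the usual determinant correction.  The transform maps the
#' mobile set onto the reference: `aligned = mobile %*% t(rotation) +
#' translation` (rows are points).
#'
#' @param mobile,reference N x 3 coordinate matrices with matched rows.
#' @return a [SuperpositionResult-class].
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("mobile and reference must be N x 3 matrices with matched rows")
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 paired points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  m0 <- sweep(mobile, 2, cm); r0 <- sweep(reference, 2, cr)
  if (svd(m0)$d[2] < 1e-8 * max(1, svd(m0)$d[1]))
    stop("degenerate point set: points are (near-)collinear")
  A <- t(m0) %*% r0
  s <- svd(A)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- m0 %*% t(R)
  rmsd <- sqrt(sum((aligned - r0)^2) / n)
  translation <- as.numeric(cr - R %*% cm)
  new("SuperpositionResult", rotation = R, translation = translation,
      rmsd = rmsd, nPairs = as.integer(n))
}

#' Superpose one chain onto another
#'
#' Convenience front end to [kabsch()] driven by a
#' [CorrespondenceMap-class]: extracts the paired atoms (C-alpha by default)
#' from the two structures and returns the optimal superposition.
#'
#' @param mobile,reference [Structure-class] objects.
#' @param map a [CorrespondenceMap-class] from [buildCorrespondence()].
#' @return a [SuperpositionResult-class].
#' @export
superposeChains <- function(mobile, reference, map) {
  stopifnot(is(map, "CorrespondenceMap"))
  mc <- .pairedCoords(mobile, map@mobileChain, map@pairs$mobileRes,
                      map@atomName)
  rc <- .pairedCoords(reference, map@refChain, map@pairs$refRes, map@atomName)
  kabsch(mc, rc)
}

#' Apply a rigid transform to a structure
#'
#' @param model a [Structure-class].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric.
#' @return the transformed [Structure-class].
#' @export
transformStructure <- function(model, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  stopifnot(is(model, "Structure"))
  a <- model@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  new("Structure", atoms = a, title = model@title,
      resolvedAltLocs = model@resolvedAltLocs)
}

#' Distance between two named atoms
#'
#' Euclidean distance in Angstrom between atoms addressed by chain, author
#' residue number and atom name.
#'
#' @param model a [Structure-class].
#' @param chainA,resA,atomA address of the first atom.
#' @param chainB,resB,atomB address of the second atom.
#' @param insertA,insertB insertion codes (default blank).
#' @return distance in Angstrom.
#' @export
atomDistance <- function(model, chainA, resA, atomA, chainB, resB, atomB,
                         insertA = "", insertB = "") {
  stopifnot(is(model, "Structure"))
  a <- model@atoms
  find <- function(chain, res, name, ins) {
    i <- which(a$chainId == chain & a$resSeq == res & a$name == name &
               a$insert == ins)
    if (length(i) == 0)
      stop("atom not found: chain ", chain, " residue ", res, " atom ", name)
    i[1]
  }
  i <- find(chainA, resA, atomA, insertA)
  j <- find(chainB, resB, atomB, insertB)
  sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
}

# Uniformly distributed random rotation matrix (Arvo's method via quaternion)
.randomRotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}
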