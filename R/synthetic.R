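# Deterministic generators for the fixture classes the test surface needs:
# analytically solvable sphere pairs, planted interface contacts, receiver
# domains in a known switch state, pockets with planted steric obstructions,
# and alignments with planted conserved columns.  All randomness is local
# (the caller's RNG state is restored) and fully determined by `seed`.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.seededRigidTransform <- function(model, seed) {
  .withSeed(seed, {
    R <- .randomRotation()
    t <- stats::runif(3, -15, 15)
    transformStructure(model, R, t)
  })
}

#' Two-sphere fixture with closed-form surface areas
#'
#' Two single-atom residues on the x axis whose accessible and buried areas
#' have spherical-cap closed forms, used as the analytic oracle for the
#' Shrake-Rupley implementation.
#'
#' @param r1,r2 van der Waals radii in Angstrom (must lie in [1, 2.5]).
#' @param separation centre-centre distance, Angstrom.
#' @return list with `model` (a [Structure-class] with chains A and B),
#'   `radii` (a matching [RadiusSet-class]) and `analytic(probe)`, a function
#'   returning the exact `sasaA`, `sasaB`, `sasaComplex` and `bsa`.
#' @export
makeTwoSphereFixture <- function(r1, r2, separation) {
  stopifnot(r1 > 0, r2 > 0, separation >= 0)
  residues <- list(
    list(resSeq = 1, resName = "SP1", chainId = "A",
         atoms = list(X = c(0, 0, 0))),
    list(resSeq = 1, resName = "SP2", chainId = "B",
         atoms = list(X = c(separation, 0, 0))))
  model <- .structureFromResidues(residues, title = "two-sphere fixture")
  radii <- radiusSet("two-sphere",
                     atomRadii = c("SP1:X" = r1, "SP2:X" = r2))
  analytic <- function(probe = 1.4) {
    a <- r1 + probe; b <- r2 + probe; d <- separation
    fullA <- 4 * pi * a^2; fullB <- 4 * pi * b^2
    if (d >= a + b) {
      capA <- 0; capB <- 0
    } else if (d <= abs(a - b)) {
      # smaller sphere entirely inside the larger one
      if (a >= b) { capA <- 0; capB <- fullB } else { capA <- fullA; capB <- 0 }
    } else {
      hA <- a - (d^2 + a^2 - b^2) / (2 * d)
      hB <- b - (d^2 + b^2 - a^2) / (2 * d)
      capA <- 2 * pi * a * hA
      capB <- 2 * pi * b * hB
    }
    list(sasaA = fullA, sasaB = fullB,
         sasaComplex = fullA - capA + fullB - capB,
         bsa = capA + capB)
  }
  list(model = model, radii = radii, analytic = analytic)
}

#' Planted two-chain contact fixture
#'
#' Two ten-residue single-atom chains; only the residues inside
#' `contactZone` are brought within surface-contact distance, so the
#' interface residue list is known by construction on both sides.
#'
#' @param nRes residues per chain.
#' @param contactZone residue numbers placed in contact.
#' @param spacing along-chain atom spacing, Angstrom.
#' @param closeZ,farZ inter-chain separations for zone and non-zone residues.
#' @return list with `model` and `contactZone`.
#' @export
makeContactFixture <- function(nRes = 10, contactZone = 4:7, spacing = 5,
                               closeZ = 5, farZ = 9.5) {
  residues <- list()
  for (i in seq_len(nRes)) {
    residues[[length(residues) + 1]] <-
      list(resSeq = i, resName = "GLY", chainId = "A",
           atoms = list(CA = c(i * spacing, 0, 0)))
    z <- if (i %in% contactZone) closeZ else farZ
    residues[[length(residues) + 1]] <-
      list(resSeq = i, resName = "GLY", chainId = "B",
           atoms = list(CA = c(i * spacing, 0, z)))
  }
  model <- .structureFromResidues(residues, title = "planted contact fixture")
  list(model = model, contactZone = contactZone)
}

#' Receiver-domain fixture in a constructed switch state
#'
#' A minimal receiver-like scaffold carrying the three observables the
#' switch-state classifier reads: a Thr-O-gamma placed toward or away from
#' the acceptor Asp C-gamma, a His side chain either solvent-exposed or
#' buried inside a closed shell of atoms, and a four-C-alpha loop laid out at
#' a requested pseudodihedral.  The `seed` applies a rigid rotation and
#' translation to the whole model, so every derived observable is preserved
#' exactly across replicates.
#'
#' @param state `"phosphorylated-like"` or `"non-phosphorylated-like"`.
#' @param seed integer seed for the rigid placement.
#' @param loopAngle requested loop pseudodihedral in degrees; defaults to 55
#'   for the phosphorylated-like and 170 for the non-phosphorylated-like
#'   state.
#' @return list with `model`, `chain`, `state`, `loopAngle` and the matching
#'   [receiverConfig()].
#' @export
makeReceiverStateFixture <- function(state = c("phosphorylated-like",
                                               "non-phosphorylated-like"),
                                     seed = 1L, loopAngle = NULL) {
  state <- match.arg(state)
  phos <- state == "phosphorylated-like"
  if (is.null(loopAngle)) loopAngle <- if (phos) 55 else 170

  ca82 <- c(0, 0, 0); ca83 <- c(3.8, 0, 0)
  ca84 <- ca83 + 3.8 * c(0.5, sqrt(3) / 2, 0)
  ca85 <- .nerf(ca82, ca83, ca84, 3.8, 120, loopAngle)
  loopCa <- list(`82` = ca82, `83` = ca83, `84` = ca84, `85` = ca85)

  bbOffsets <- list(N = c(-0.8, -1.0, 0.5), C = c(0.9, 1.0, 0.4),
                    O = c(1.2, 1.9, -0.3))
  residues <- list()
  addRes <- function(resSeq, resName, atoms)
    residues[[length(residues) + 1]] <<-
      list(resSeq = resSeq, resName = resName, chainId = "R", atoms = atoms)

  # acceptor aspartate
  cg54 <- c(0, -6.5, 0)
  cb54 <- cg54 + c(0.2, -1.4, 0.3)
  ca54 <- cb54 + c(1.0, -1.0, 0.2)
  addRes(54, "ASP", list(N = ca54 + c(-0.9, -1.0, 0.3), CA = ca54,
                         C = ca54 + c(1.4, 0.5, -0.3),
                         O = ca54 + c(1.8, 1.5, -0.6),
                         CB = cb54, CG = cg54,
                         OD1 = cg54 + c(1.0, 0.7, 0),
                         OD2 = cg54 + c(-1.0, 0.7, 0.2)))

  # switch threonine (= first loop residue)
  cb82 <- c(0, -1.2, 0.9)
  u <- cg54 - cb82; u <- u / sqrt(sum(u^2))
  og1 <- if (phos) cb82 + 1.43 * u else cb82 - 1.43 * u
  addRes(82, "THR", list(N = ca82 + bbOffsets$N, CA = ca82,
                         C = ca82 + bbOffsets$C, O = ca82 + bbOffsets$O,
                         CB = cb82, OG1 = og1,
                         CG2 = cb82 + c(1.2, 0, 0.8)))
  for (r in 83:85) {
    ca <- loopCa[[as.character(r)]]
    addRes(r, "GLY", list(N = ca + bbOffsets$N, CA = ca,
                          C = ca + bbOffsets$C, O = ca + bbOffsets$O))
  }

  # switch histidine, well separated from the loop and acceptor
  hisBB <- list(N = c(9, -7.8, 3), CA = c(10, -7, 3), C = c(11.2, -7.7, 3.2))
  hisSide <- buildSideChain("HIS", hisBB, c(-60, 80))
  addRes(101, "HIS", c(hisBB, list(O = hisBB$C + c(0.3, -1.1, 0.3)), hisSide))

  if (phos) {
    # closed shell burying the His side chain
    centroid <- colMeans(do.call(rbind, hisSide))
    shell <- sweep(4.0 * fibonacciSphere(140), 2, centroid, "+")
    for (k in seq_len(nrow(shell)))
      residues[[length(residues) + 1]] <-
        list(resSeq = 500 + k, resName = "UNK", chainId = "Z",
             atoms = list(C1 = shell[k, ]))
  }

  model <- .structureFromResidues(residues,
                                  title = paste("receiver fixture:", state))
  model <- .seededRigidTransform(model, seed)
  list(model = model, chain = "R", state = state, loopAngle = loopAngle,
       config = receiverConfig())
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
           "Q", "R", "S", "T", "V", "W", "Y")

#' Alignment fixture with planted conserved columns
#'
#' Generates an aligned (gap-free) protein family from a random ancestor:
#' planted columns are copied unchanged into every sequence, all other
#' columns mutate independently at `mutationRate` per sequence.
#'
#' @param nSeqs number of sequences.
#' @param length alignment width.
#' @param conservedColumns columns kept identical across all sequences.
#' @param mutationRate per-site substitution probability outside the planted
#'   columns.
#' @param seed integer seed.
#' @param ids sequence identifiers; the first is the reference.
#' @return list with `text` (aligned FASTA), `sequences`, `profile` (an
#'   [MsaProfile-class] with the first sequence as reference),
#'   `conservedColumns`, `mutationRate` and `seed`.
#' @export
makeMsaFixture <- function(nSeqs = 6, length = 60, conservedColumns = integer(0),
                           mutationRate = 0.3, seed = 1L,
                           ids = sprintf("seq%02d", seq_len(nSeqs))) {
  stopifnot(all(conservedColumns %in% seq_len(length)), nSeqs >= 2)
  seqs <- .withSeed(seed, {
    ancestor <- sample(.AA20, length, replace = TRUE)
    out <- matrix("", nrow = nSeqs, ncol = length)
    out[1, ] <- ancestor
    mutable <- setdiff(seq_len(length), conservedColumns)
    for (i in seq_len(nSeqs)[-1]) {
      s <- ancestor
      hit <- mutable[stats::runif(base::length(mutable)) < mutationRate]
      for (j in hit) s[j] <- sample(setdiff(.AA20, s[j]), 1)
      out[i, ] <- s
    }
    out
  })
  sequences <- apply(seqs, 1, paste, collapse = "")
  names(sequences) <- ids
  text <- paste0(">", ids, "\n", sequences, collapse = "\n")
  list(text = text, sequences = sequences,
       profile = msaProfile(sequences, ids[1]),
       conservedColumns = sort(conservedColumns),
       mutationRate = mutationRate, seed = seed)
}

#' Pocket fixture with a planted steric obstruction
#'
#' A mutable backbone stub surrounded by a closed spherical shell of atoms at
#' `pocketRadius` from its C-beta: a tight shell clashes with every rotamer
#' of any side chain reaching beyond C-beta, a wide shell clashes with none,
#' so the clash-free fraction of [mutateAndScan()] is known by construction.
#'
#' @param pocketRadius shell radius from the C-beta, Angstrom.
#' @param mutationSite residue number of the stub.
#' @param seed integer seed for the rigid placement of the whole fixture.
#' @param nShell number of shell atoms.
#' @return list with `model`, `chain` and `position`.
#' @export
makePocketFixture <- function(pocketRadius, mutationSite = 50L, seed = 1L,
                              nShell = 240) {
  stopifnot(pocketRadius > 0)
  bb <- .extendedBackbone(1)[[1]]
  cb <- .idealCB(bb$N, bb$CA, bb$C)
  residues <- list(
    list(resSeq = mutationSite, resName = "ALA", chainId = "P",
         atoms = c(bb, list(CB = cb))))
  shell <- sweep(pocketRadius * fibonacciSphere(nShell), 2, cb, "+")
  for (k in seq_len(nrow(shell)))
    residues[[length(residues) + 1]] <-
      list(resSeq = k, resName = "UNK", chainId = "S",
           atoms = list(C1 = shell[k, ]))
  model <- .structureFromResidues(residues, title = "pocket fixture")
  model <- .seededRigidTransform(model, seed)
  list(model = model, chain = "P", position = as.integer(mutationSite),
       pocketRadius = pocketRadius)
}
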