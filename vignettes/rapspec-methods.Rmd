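---
title: "rapspec: methods, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rapspec: methods, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents what `rapspec` computes, why each default
parameter has the value it has, what the synthetic fixtures do and do not
emulate, and where the methods stop being trustworthy.

## The analysis model

`rapspec` re-implements a structural-bioinformatics workflow for
phosphatase-substrate complexes between Rap-family regulators and the
receiver-domain protein Spo0F:

1. quantify the protein-protein interface of a complex (buried surface
   area and per-residue interface membership);
2. superpose crystallographic copies and measure receiver-domain switch
   observables (switch-residue orientation/burial, beta4-alpha4 loop
   pseudodihedral);
3. map alignment-column conservation over a training set of demonstrated
   phosphatases onto the structural interface;
4. predict whether a candidate Rap protein is a Spo0F phosphatase from
   (a) identity at the conserved interfacial positions, (b) a catalytic
   Gln/Glu rule, and (c) rotamer clash scanning of the mismatched
   substitutions in the complex.

## Surface areas

`shrakeRupleySasa()` implements Shrake-Rupley numerical SASA. Test points
are a **deterministic Fibonacci (golden-angle) lattice**
(`fibonacciSphere()`), not random sampling: the computation involves no
RNG, so identical inputs give bit-identical areas on every platform.

* **Probe radius 1.4 Å** — the conventional water probe.
* **960 points per atom** — at this density an isolated sphere's area is
  exact to well under 0.5 % and two-sphere buried areas agree with the
  closed-form spherical-cap solution to better than 1 % (both are enforced
  by the acceptance tests); doubling the density changes totals by less
  than 2 %. The count is a speed/accuracy compromise chosen before any
  validation against published values.
* **Radii** (`defaultRadiusSet()`): united-heavy-atom radii in the
  Chothia/NACCESS tradition — aliphatic C 1.87 Å, trigonal/carbonyl C
  1.76 Å, N 1.65 Å, O 1.40 Å, S 1.85 Å, P 1.90 Å. Hydrogens are implicit;
  hydrogen, water and hetero records are excluded from SASA.

Buried surface area between chain groups A and B is
`SASA(A) + SASA(B) - SASA(A+B)`, i.e. the **total over both sides** (not
halved). A residue is an interface residue when its per-residue delta-SASA
exceeds **1.0 Å²** — small enough to catch rim residues, large enough to
ignore lattice noise of the point sampling; the published interface
residue list is treated as the calibration surface for this threshold, not
as training data for any other parameter.

## Superposition and torsions

`kabsch()` is the SVD solution with the determinant correction, refusing
(near-)collinear point sets instead of returning an ill-conditioned
rotation. The convention is `aligned = mobile %*% t(rotation) +
translation`. `dihedralAngle()` uses the atan2 formulation with the IUPAC
sign convention (cis = 0, trans = 180) and is validated against two
independent formulations; `pseudodihedralCa()` applies it to four
consecutive C-alpha atoms and returns `NA` — "disordered" — when any
C-alpha is unmodeled, rather than silently substituting.

## Switch-state classification

`classifyReceiverState()` reads two binary axes plus one reported-only
observable, with Spo0F defaults in `receiverConfig()`:

* **Hydroxyl switch** (Thr82): O-gamma within **5.5 Å** of the acceptor
  Asp54 C-gamma counts as "toward" the active site. The cutoff sits
  between typical rotated-inward distances (3-5 Å) and rotated-outward
  distances (> 6.5 Å) of receiver-domain structures.
* **Aromatic switch** (His101): side-chain SASA relative to the same side
  chain in an extended Gly-X-Gly reference peptide at or below **0.15**
  counts as "internal" — the common buried/exposed boundary for relative
  accessibility.
* **Loop pseudodihedral** (residues 82-85) is reported but never drives
  the label, so a disordered loop cannot flip a classification.

The overall label is phosphorylated-like only when both axes agree
(toward + internal), non-phosphorylated-like only for away + external,
and "mixed" otherwise, including when an axis is indeterminate because
atoms are unmodeled.

## Conservation and the specificity verdict

`columnConservation()` deliberately replaces phylogeny-weighted scoring
with a transparent frequency: a column's score is the frequency of its
modal residue among the training sequences (gaps never match). The
training set is the set of proteins demonstrated to dephosphorylate the
substrate — six sequences in the reference use case.

* **Conservation threshold 5/6** — with six training sequences this is the
  smallest threshold that still tolerates a single disagreeing sequence;
  it was fixed a priori from that consideration alone.
* **Identity threshold 12/18 (2/3)** for the verdict — chosen midway
  between the observed identity of known non-phosphatases (about one
  third) and known phosphatases (above four fifths), so the decision
  boundary is far from both classes.
* **Catalytic rule** — Gln or Glu required at the position equivalent to
  the reference catalytic glutamine (position 47 in the reference
  numbering); anything else, including a gap, is disqualifying.

`mutateAndScan()` models a substitution by sweeping a canonical rotamer
library on the **fixed native backbone** against a **fixed environment**
(hard-sphere model, worst pairwise overlap `(r_i + r_j) - d`, tolerance
**0.4 Å**, the common steric-clash convention). A substitution whose every
rotamer clashes is treated as structurally blocked. This is deliberately
conservative: no backbone relaxation, no environment repacking, no
energetics — it can only flag gross steric impossibility, which is exactly
the role it plays in the verdict. Proline is unsupported (its backbone
ring cannot be modeled by side-chain placement alone) and is an explicit
error.

`predictPhosphatase()` combines the axes deterministically:
non-phosphatase if the catalytic rule fails, identity falls below the
threshold, or any mismatched substitution is fully clash-blocked;
indeterminate if the sequence rules pass but no structure was available to
scan the mismatches; phosphatase otherwise.

## Synthetic fixtures: what they emulate, and what they do not

The generators in `R/synthetic.R` exist so that every stage has a test
with a known answer and no external inputs:

* `makeTwoSphereFixture()` — two single-atom residues whose SASA/BSA have
  closed-form spherical-cap solutions; the oracle for the numerical SASA.
* `makeContactFixture()` — two chains where only a planted residue zone is
  within surface-contact distance; the interface-detection oracle.
* `makeReceiverStateFixture()` — a minimal receiver-like scaffold carrying
  exactly the observables the classifier reads (a hydroxyl placed toward
  or away, a His side chain exposed or enclosed in a shell, a loop at a
  requested pseudodihedral), rigidly placed by seed so every observable is
  preserved exactly across replicates.
* `makePocketFixture()` — a mutable backbone stub inside a closed shell
  whose radius makes the clash-free fraction 0 or 1 by construction.
* `makeMsaFixture()` — an aligned family from a random ancestor with
  planted invariant columns and a per-site mutation rate.

These fixtures emulate the *geometry and bookkeeping* of the real inputs
(standard PDB and aligned-FASTA formats, realistic bond lengths where it
matters). They do **not** emulate protein energetics, realistic packing
density, sequence covariation, or crystallographic artefacts; problem
sizes (tens of residues, hundreds of shell atoms) are chosen for
desk-scale test runtimes, which is a package choice, not a claim about
real proteins.

## Numerical choices

* All randomness in fixture generation is seed-controlled and restores the
  caller's RNG state; given a seed, generation is byte-identical.
* The SASA and worst-overlap kernels are C++ (via Rcpp) with
  neighbour-list pruning; everything else is plain R.
* Angles are degrees, distances Angstrom, areas Å² throughout.

## Limitations

* Published buried-area values depend on the radii set and point density
  of the original software; the acceptance tolerance is ±10 % for that
  reason.
* The conservation score ignores phylogeny; closely related training
  sequences are over-weighted relative to a tree-aware method.
* The clash scan cannot detect substitutions that are tolerated
  sterically but disruptive energetically, nor rescue by backbone
  movement; its verdict contribution is one-sided (only ever
  disqualifying).
* The switch-state classifier assumes the receiver-domain numbering of
  its configuration; apply `receiverConfig()` with the correct equivalent
  positions for other proteins.
* Validation against the published complex requires supplying the
  deposited structure and public sequences (see the README); those checks
  are intentionally red until the files are provided.
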