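# rapspec

Structure- and sequence-based analysis of how Rap-family regulators
recognise and dephosphorylate the sporulation phosphorelay response
regulator Spo0F.

The package provides, as composable S4 building blocks:

- **Structure handling** — a fixed-column PDB reader/writer
  (`readPDB()`, `writePDB()`), alternate-location resolution
  (`resolveAltLocs()`), and chain-group selections (`chainGroup()`,
  `selectAtoms()`).
- **Surface areas and interfaces** — a deterministic Shrake–Rupley
  solvent-accessible surface area implementation (`shrakeRupleySasa()`,
  Fibonacci sphere lattice, C++ kernel), buried surface area between chain
  groups (`buriedSurfaceArea()`), and per-residue interface detection
  (`interfaceResidues()`).
- **Superposition and torsions** — Kabsch least-squares superposition
  (`kabsch()`, `superposeChains()`), signed dihedrals (`dihedralAngle()`),
  and the four-C-alpha loop pseudodihedral (`pseudodihedralCa()`).
- **Receiver-domain switch states** — classification of a receiver-domain
  copy as phosphorylated-like or non-phosphorylated-like from its hydroxyl
  switch orientation, aromatic switch burial and beta4–alpha4 loop angle
  (`classifyReceiverState()`).
- **Conservation and specificity** — alignment-column conservation over a
  training set of demonstrated phosphatases (`columnConservation()`),
  intersection with the structural interface
  (`conservedInterfacePositions()`), candidate scoring
  (`scoreCandidate()`), the catalytic Gln/Glu rule (`catalyticCheck()`),
  rotamer clash scanning of point substitutions (`mutateAndScan()`), and a
  rule-based phosphatase verdict (`predictPhosphatase()`).
- **Synthetic fixtures** — deterministic generators with analytically known
  answers (`makeTwoSphereFixture()`, `makeContactFixture()`,
  `makeReceiverStateFixture()`, `makeMsaFixture()`, `makePocketFixture()`)
  that let every stage be validated without downloading anything.
- **Pipelines and CLI** — end-to-end orchestration
  (`runStructureReport()`, `runSpecificityPipeline()`) driven by a flat
  YAML configuration, with full provenance embedded in every JSON report,
  plus an `inst/exec/rapspec` command-line front end
  (subcommands: `parse`, `bsa`, `interface`, `superpose`,
  `pseudodihedral`, `switch`, `conserve`, `predict`, `mutscan`,
  `simulate`, `report`).

## Worked example

Build a synthetic receiver domain in a known switch state, classify it,
recover a planted interface, and clash-scan a mutation in a planted tight
pocket:

```r
library(rapspec)

fx <- makeReceiverStateFixture("phosphorylated-like", seed = 1)
classifyReceiverState(fx$model, fx$chain, fx$config)
#> Chain R: phosphorylated-like (Thr switch toward, His switch internal, loop 55.0 deg)

cf <- makeContactFixture()            # residues 4-7 placed in contact
interfaceResidues(cf$model, chainGroup("A"), chainGroup("B"))
#> Interface A | B: total BSA 126.5 A^2
#>   4 residues on side A, 4 on side B above 1.00 A^2

tight <- makePocketFixture(3, seed = 1)  # obstruction shell at 3 A
mutateAndScan(tight$model, tight$chain, tight$position, "HIS")
#> P50 -> HIS: clash-free fraction 0.00 (8 rotamers, cutoff 0.40 A)
```

The same operations run end to end from a YAML configuration:

```r
cfg <- pipelineConfig(pdb = "complex.pdb", msa = "family.fasta",
                      groupA = "A", groupB = c("B", "C", "D"),
                      referenceId = "RapH",
                      trainingIds = c("RapA", "RapB", "RapE", "RapH",
                                      "BXA0205", "BA3790"),
                      candidateIds = c("RapJ", "RapD", "RapF"),
                      scanChain = "A")
report <- runSpecificityPipeline(cfg)
writeReportJSON(report, "specificity.json")
```

or from the shell:

```sh
rapspec predict --config pipeline.yaml --out specificity.json
```

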