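# epigraft

Structure-guided **epitope grafting** and **proteome-wide deimmunization**
for immunogen design, in R.

Self-antigens make poor vaccine immunogens: tolerance suppresses the
response, and any response raised risks autoreactivity. One way around this
is to present the *functional surface* of a self-protein on a distant
homolog — transplant the epitopes that matter onto a scaffold divergent
enough to be seen as foreign, then remove every residual peptide the host
could read as "self". `epigraft` implements that design computation as a
reusable pipeline:

1. **Footprint** — from complex structures of the antigen bound to each
   partner (a receptor, therapeutic antibodies), compute per-residue buried
   surface area (BSA) by the Shrake–Rupley method:
   `BSA(res) = Σ_atoms [SASA(antigen alone) − SASA(complex)]`,
   with SASA evaluated on a deterministic golden-spiral quadrature
   (default 960 points, probe 1.4 Å).
2. **Stretch selection** — positions with `BSA ≥ 1 Å²` against a partner
   are "contacted"; positions contacted by at least `min_partners`
   (default 2) partners are merged into contiguous epitope stretches,
   bridging up to `gap_merge` (default 2) intervening residues.
3. **Graft** — a global donor↔scaffold alignment (BLOSUM62, gap open 11 /
   extend 1) maps each stretch onto the scaffold, which receives the donor
   residues (substitutions, insertions and deletions are recorded in a
   `GraftPlan`).
4. **Deimmunize** — every 9-residue window of the grafted sequence that
   occurs identically in a reference proteome is eliminated by greedy
   point mutation: each step applies the (position, replacement) that
   destroys the most matched windows without creating a new one, drawing
   replacements only from residues observed in a species-variant alignment
   and never touching the transplanted epitope.
5. **Liability variants** — named substitutions (e.g. removing protease
   cleavage sites, `K21Q`/`R218E` style) are applied with a from-residue
   guard, and the final construct is re-verified by a full rescan.

A seeded synthetic-data module (decoy proteomes with planted windows, toy
two-chain complexes with controllable interface geometry, species-variant
alignments with recorded column truth) makes the whole pipeline testable
offline with known ground truth.

## Worked example

```r
library(epigraft)

fx  <- syntheticFixture(7)          # donor + 2 partner complexes + decoys
dir <- tempfile()
cfg <- writeFixture(fx, dir)        # PDB/FASTA/YAML on disk
rep <- runPipeline(cfg)
rep
#> epigraft design report
#>   status:         clean
#>   stretches:      2
#>   mutations:      2
#>   residual self windows: 0/12
#>   epitope intact: TRUE
#>   final length:   20
```

The two partner complexes bury donor spans 5–8 and 12–14; both spans clear
the two-partner quorum and become epitope stretches. Grafting writes the
donor residues onto the scaffold; the two proteome windows planted at
grafted positions 1 and 11 are each destroyed by one pooled mutation
outside the epitope; the final rescan finds zero shared 9-mers
(`residual self windows: 0/12`) and the transplanted surface is untouched
(`epitope intact: TRUE`). Stage outputs (`footprint.tsv`, `stretches.tsv`,
`graft_plan.json`, `mutations.tsv`, `design_report.json`,
`final_construct.fasta`, `run.log`) land in `<dir>/out/`.

The same stages are exported individually (`loadStructure`,
`computeSasa`, `perResidueBsa`, `buildFootprint`, `selectEpitopeStretches`,
`alignDonorScaffold`, `transplantStretches`, `buildKmerIndex`,
`scanSequence`, `buildSubstitutionPool`, `dehumanize`, `applyVariants`,
`evaluateDesign`), and `inst/scripts/epigraft.R` offers a thin shell entry
point (`run`, `synth`, `scan`).

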