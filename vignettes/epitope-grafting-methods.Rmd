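---
title: "Methods: epitope grafting and proteome-wide deimmunization"
author: "epigraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epitope grafting and proteome-wide deimmunization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigraft)
```

## The design problem

A self-protein such as PCSK9 is a hard vaccination target: the immune
system is tolerant of it, and antibodies that do arise risk autoreactivity
beyond the surface one actually wants blocked. The mimic-design strategy
implemented here sidesteps tolerance by rebuilding only the *functionally
relevant surface* of the antigen on a divergent homolog scaffold, and then
erasing every peptide-level trace of "self" from the rest of the molecule.
Two definitions anchor the computation:

* **Epitope-critical residues** are donor positions buried by at least
  `minPartners` independent binding partners in complex structures —
  burial being measured as per-residue buried surface area (BSA).
* **Self-peptides** are 9-residue windows of the designed sequence that
  occur *identically* anywhere in a reference proteome — a conservative,
  assumption-free proxy for potential T-cell self-epitopes (9 is the
  canonical MHC-I core length).

A design is accepted when it carries the donor epitope stretches verbatim
and contains **zero** such shared windows.

## Buried surface area

SASA is computed with the Shrake–Rupley method: each atom's van der Waals
sphere is expanded by the probe radius (1.4 Å, water), `nPoints`
quasi-uniform points are placed on the expanded sphere, and the exposed
fraction — points outside every neighbouring expanded sphere — is
converted to area. Then, per residue,

$$\mathrm{BSA} = \sum_{\text{atoms}}
  \bigl[\mathrm{SASA}_{\text{antigen alone}} -
        \mathrm{SASA}_{\text{complex}}\bigr],$$

clamped at zero.

Numerical choices:

* **Point set.** A golden-spiral (Fibonacci) lattice — deterministic, with
  near-uniform point weights. At the default `nPoints = 960` the
  single-sphere area is reproduced essentially exactly and the two-sphere
  spherical-cap closed form within 2 % across the van der Waals range;
  these checks run in the test suite and the acceptance script.
* **Orientation convention.** The point lattice is oriented in a canonical
  frame built from the principal axes of the reference coordinates (signs
  fixed by third moments, right-handed completion). Because the frame is
  equivariant under rigid motion, SASA is invariant under rotation and
  translation of the model for configurations with non-degenerate
  principal axes; for degenerate ones (a single atom, collinear chains)
  the residual orientation freedom only moves results within quadrature
  noise.
* **Shared frame for BSA.** Both SASA passes of a BSA evaluation reuse one
  frame, so for residues out of reach of every partner atom the two
  per-point exposure patterns are *identical* and BSA is exactly zero, not
  zero-within-noise. Negative per-residue sums (pure quadrature noise,
  possible only at contact residues) are clamped.
* **Radii.** A fixed published element table (Bondi 1964); unknown
  elements fall back to 1.8 Å with a warning that is collected into the
  pipeline report.
* **Structure hygiene.** Only polymer protein atoms enter the computation:
  waters, ions, glycans and other hetero groups are dropped at parse time.
  Alternate locations keep the highest-occupancy conformer (ties broken by
  altloc identifier). Unmodeled donor positions get BSA 0 and are flagged
  per partner in the profile rather than silently merged.
* **Numbering.** Structure author numbering is mapped to 1-based donor
  positions by aligning each chain's extracted sequence to the donor
  (global on the chain, local on the donor). A chain mapping below 80 %
  identity over aligned columns is a hard error — in practice that always
  indicates a chain-assignment or numbering mix-up, and a silently wrong
  map would corrupt every downstream stage.

## Stretch selection

No universal BSA cutoff defines "contacted", so the threshold is an
explicit, configurable parameter defaulting to 1 Å² per residue per
partner — low enough to keep genuine peripheral interface residues, high
enough to suppress quadrature-level noise. Positions contacted by at least
`minPartners = 2` partners are critical; runs of critical positions
separated by at most `gapMerge = 2` non-critical residues are merged into
one stretch, since a transplantable surface patch should not be fragmented
by a single uncontacted side chain. Both parameters are echoed into every
report; raising either can only shrink the critical set (a property the
tests enforce). Selection is independent of partner order, and each
stretch records the union of partners supporting it.

## Grafting

Donor and scaffold are aligned globally (Needleman–Wunsch via Biostrings)
under BLOSUM62 with gap open 11 / extend 1 — the standard protein scoring
for homologs in the 30–70 % identity band where scaffold candidates live.
The traceback is deterministic, so the grafted sequence is a pure function
of its inputs. Within the aligned span of a stretch the grafted sequence
is the donor residues: scaffold mismatches become substitutions, scaffold
gaps insertions, donor gaps deletions — all recorded in the `GraftPlan`
together with a complete position map from grafted positions back to the
scaffold. Outside stretch spans the scaffold is untouched. The plan also
stores the expected epitope residues, making "epitope intact" a mechanical
check on any later sequence.

## Deimmunization

The reference proteome is indexed exactly: every 9-mer window maps to all
its source proteins. `X` (unknown residue) poisons any window containing
it on both sides — an unknown residue can never *support* a claimed match.
Ambiguity codes (`B`, `Z`, `J`, `U`, `O`) are rejected outright rather
than remapped, and the proteome's md5 digest travels with every report
because the reference set is an input, not a constant.

Mutations are drawn from a **substitution pool**: at each position, the
residues observed at least `minCount` times in the corresponding column of
a species-variant alignment of the scaffold, weighted by their counts.
Evolution has already tested these residues in this structural context,
which is the cheapest available proxy for mutations the fold will
tolerate. Positions inserted by the graft have no scaffold column of their
own; they inherit the nearest scaffold column's pool and are flagged as
such in the pool object.

The greedy loop then repeats: rescan; score every legal move — a mutable
position covered by at least one matched window, replaced by a pool
residue such that **none** of the up-to-9 newly created windows is an
index key (checked exactly); apply the move destroying the most matched
windows, breaking ties by higher pool weight, then lower position, then
alphabetical replacement — fully deterministic. Every applied move
destroys at least one window and creates none, so the match count strictly
decreases and the loop terminates in at most the initial number of matched
windows. Exhaustion of legal moves yields status `infeasible` with the
offending windows reported; exceeding `maxMutations` (default 50, roomy
for a realistically divergent scaffold) yields `budget_exhausted`. Failure
is a status, never an exception, and the final sequence is always
re-verified by a full rescan.

Greedy set cover is not optimal in general, but two useful guarantees
hold and are exercised by the tests: a single move that clears everything
is always found when one exists (it maximizes the objective), so
one-window fixtures and overlapping-window fixtures are solved optimally;
and the mutation count never exceeds the initial window count.

Named liability variants (e.g. removing experimentally identified
cleavage sites) are applied *after* deimmunization with a from-residue
guard that catches numbering-convention mistakes; the final construct is
rescanned afterwards, so a variant that re-created a self-window would be
visible in the report.

## The synthetic-data module

The generator produces the three input classes with recorded ground truth:

* **Decoy proteomes** — uniform sequences over a configurable alphabet;
  chosen query windows are copied in (`plantSharedWindows`), with
  contradictory overlapping plants rejected. Disjoint-alphabet settings
  make chance collisions impossible, giving exact negative controls.
* **Toy complexes** — straight chains of single-sphere residues (1.9 Å,
  carbon-like) at 3.8 Å spacing, with partner chains placed at a chosen
  distance from a chosen contact span. All geometric expectations reduce
  to the closed-form spherical-cap oracle. Sphere packing makes perfectly
  sharp footprints non-trivial: any partner sphere within contact distance
  of residue *i* sits within the occlusion horizon of residues *i*±1, so
  span-edge partner spheres lean inward just enough (0.1 Å beyond the
  horizon) that every off-span residue buries exactly nothing. Parameter
  combinations where that is impossible (very small distances, an
  interior one-residue span) raise a "geometrically impossible" error
  rather than generating a fixture that contradicts its own truth.
* **Species alignments** — per-column independent substitution at a stated
  rate, no indels, with per-column residue counts returned as truth.

Each generator consumes one seeded stream in a documented order, and the
default geometry is seed-independent (the seed only drives optional
jitter), so fixtures regenerate byte-identically. The bundled end-to-end
fixture (`syntheticFixture`) uses a 20-residue donor with spans 5–8 and
12–14 contacted by two partner complexes, a scaffold diverged at rate 0.3,
an 8-row species alignment at substitution rate 0.1, and a 12-protein
decoy proteome with two grafted-sequence windows planted — small enough
that every stage's expected outcome is hand-checkable, large enough to
exercise every code path; the alignment is nudged where necessary so each
planted window overlaps a mutable position with a non-empty pool, keeping
the deimmunization stage feasible by construction.

What the toys deliberately do **not** emulate: realistic folds or packing
(single-sphere residues), realistic proteome composition (uniform
letters), phylogenetic correlation between variant rows, or missing
residues and altlocs in generated coordinates (those paths are covered by
hand-written structure fixtures instead). Passing on synthetic data
therefore demonstrates correctness of the computation, not biological
performance of any particular design.

## Problem sizes and determinism

The shipped suites run at desk scale: closed-form SASA checks on one- and
two-sphere systems at 960 points; oracle comparison of the window scan
over 200 random proteome/query pairs (up to 12 proteins × 70 residues);
100 planted deimmunization fixtures; 60 randomized graft fixtures; and the
end-to-end fixture above — a few minutes in total. The acceptance script
(`scripts/acceptance.R --seed N --out f.json`) recomputes all of it from
one seed; every random draw derives from that seed, and the end-to-end
stage is run twice from independently regenerated fixtures to confirm
byte-level reproducibility of the report.

## Known limitations

* Burial is the only structural signal: no energetics, electrostatics or
  docking, so a residue that is buried but energetically irrelevant still
  counts as critical, and mutation tolerance is judged purely by observed
  species variation, not ΔΔG.
* Exact 9-mer identity is a conservative self-screen; near-identical
  windows (including I/L equivalence) and MHC-binding predictions are out
  of scope by design.
* Greedy mutation selection can exceed the true minimum on three or more
  heavily entangled windows, though never the initial window count.
* The BSA threshold, partner quorum and gap rule defaults are calibrated
  working values, echoed into every report precisely so that a user can
  re-run a design under different definitions of "contacted".
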