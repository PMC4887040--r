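---
title: "Active-site matching by kinematic loop closure: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-site matching by kinematic loop closure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sitematch)
```

This vignette is the package's own account of the science it implements:
the active-site model, the kinematic closure machinery, the pruning and
ranking rules, the repacking energy model, and — importantly — which
numerical and design choices were genuinely open and how they were
resolved. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. The complex active-site model

A catalytic motif declares residue *roles* in three classes: the catalytic
residues proper, residues that stabilize the catalytic residues, and
residues that bind the transition state (TS). Each role interacts either
through its side chain (and then carries χ-torsion freedom) or through its
backbone amide (and then carries no torsional freedom at all — the scaffold
either presents the amide in the right place or it does not). Restricting a
motif to its catalytic roles yields the *minimal* model; since the minimal
constraint set is a subset of the complex one, every placement admitted by
the complex model is admitted by the minimal model, and match counts can
only shrink when stabilizing roles are added. The matching tests assert
this subset property directly.

Constraints are distances (Å), angles (degrees) and improper dihedrals
(degrees), each with an optimal value and a tolerance. Deviation *beyond*
tolerance is what defines satisfaction; dihedral differences are wrapped to
the shortest arc. Mixing units in a single score requires a normalization:
1 Å is equated with 10°, a configurable convention chosen so that typical
tolerances (±0.3 Å, ±15–20°) carry comparable weight.

The shipped motif files use surrogate optima and tolerances (±0.3 Å
distances; ±15–20° angles and impropers; ±40° for the nearly-linear
donor–hydrogen–acceptor angles, whose optimum is 180° and which therefore
deviate only to one side). They are curated values in the style of
published matching parameter tables, not reproductions of any specific
table. Two classes of constraint deserve comment because they are easy to
omit and their absence is structurally visible:

* *attachment-pinning* terms (the improper around the nucleophile–TS
  pseudo-bond, the donor-approach angles at the oxyanion) remove the
  rigid-body degeneracies of the TS — without them the admissible TS poses
  form a wide manifold and near-mirror placements satisfy every remaining
  constraint;
* *ring-orientation* impropers for histidine (the imidazole plane relative
  to its two hydrogen-bond partners) pin the one internal spin that the
  hydrogen-bond distances alone cannot see.

The nucleophile–TS distance is modelled at 2.6 Å — a near-attack
arrangement rather than a formed covalent bond — so that the same geometry
remains sensible under the non-bonded energy model used for repacking.

## 2. Kinematic loops and closure

All geometry lives in one Z-matrix engine (compiled): every placed atom is
defined by three previously placed atoms plus a bond length, bond angle and
torsion. Bond lengths and angles are immutable during closure; the
optimization variables are free torsions (side-chain χ, TS rotatable bonds,
rigid-body orientation spins around pseudo-bonds) and *bounded* parameters
— exactly those angles/impropers that a motif constraint restricts, boxed
to `optimal ± tolerance`. Constraint distances are frozen at their optimum
and act as pseudo-bond lengths; their tolerance is deliberately not
explored (the freedom lives in the angular terms), which mirrors the
pseudo-bond construction and is noted as an approximation.

The main loop for a site pair is built forward through the first residue,
enters the TS through the attachment pseudo-bond, leaves through the second
link constraint, and walks the second side chain *in reverse* down to the
site-2 backbone. Side loops are built the same reversed way from their
placed partner atom back to their own anchor, which lets the
hydrogen-bond angle and improper constraints at the partner map onto
bounded torsions of the first chain rows instead of becoming blind
post-hoc filters.

Closure minimizes the squared deviation of the terminal CA plus an
orientation penalty on the terminal N and C (a frame, not just a point),
via `stats::optim(method = "L-BFGS-B")` over the DOF vector with analytic
forward kinematics and central-difference gradients in C++. A weak
quadratic pull (`1e-3` per squared degree) draws bounded parameters toward
their optima: the closure manifold generally has residual dimensions, and
the penalty selects the manifold point nearest the constraint optima
without trading off the anchor targets. The default closure tolerance is
0.1 Å on the terminal CA with 2× that on the orientation atoms;
"high-accuracy closure" is not a printed number anywhere, so this is the
package's own calibration, configurable per run.

The extended CCD closer is the baseline: the classic analytic
one-torsion-at-a-time update generalized to multiple target points, with
bounded angles relaxed by a bounded scan. The acceptance harness compares
the two on paired perturbation trials; the quasi-Newton closer must succeed
at least wherever CCD does.

Multistart uses a per-DOF grid (staggered −60/60/180 for sp3-like bonds,
±90 for sp2-like spins), deterministically subsampled under the run seed
when the full grid exceeds the cap (72 starts for main loops, 24 for side
loops by default). A hybrid strategy makes this affordable: every start is
warmed by a few cheap CCD sweeps and only promising starts are polished by
the quasi-Newton optimizer; a loop whose best warm objective stays high is
abandoned early. These caps are quality/effort knobs of the search, chosen
so a full fixture matches in roughly ten seconds on one CPU core.

## 3. Pruning and ranking

Maximum reach is computed exactly as specified operationally: the closure
optimizer is run against a dummy target 1,000 Å along the anchor–anchor
direction, from an all-extended start plus grid starts, and the largest
achieved start-to-terminal distance is the bound. A Monte-Carlo soundness
harness (1,000 random conformations per loop) verifies the bound on every
fixture. Reach pruning discards a site pair when this bound plus a margin
(0.5 Å, absorbing optimizer slack) is below the true anchor separation.

The repulsion model is a per-pair linear ramp, zero beyond an onset at
`c = 0.85` of the summed van der Waals radii and `k = 10` PEU at full
collapse, summed over heavy-atom pairs of disjoint groups. "Backbone" means
main-chain atoms of candidate-site residues, "template" all atoms of
non-candidate residues; a group's own residues are excluded so bonded and
1–3 pairs never enter. PEU is defined as the unit of this model; absolute
energies from other force fields are not comparable. The four stage
thresholds (150/30/200/50 PEU) are kept as the published operating point of
the pruning cascade; with the constants above, planted ground truths pass
all four stages, which is the calibration requirement the tests enforce.
The threshold sentence that the cascade is drawn from lists the 50-PEU
entry ambiguously; it is read here as match-vs-backbone, parallel to the
loop-stage split.

Duplicate elimination is greedy and streaming (a loop is kept iff its
no-fit RMSD to every kept loop exceeds 0.5 Å), so the kept set depends only
on input order, and every discarded loop provably has a kept neighbour.

Ranking was genuinely open: no ranking criterion is printed in the sources
this design follows. Deviation-beyond-tolerance is zero for every admitted
match by definition, so it cannot rank them; the package ranks by the
unit-normalized RMS deviation of all constraints *from their optima* plus
`repulsion/100`, with configurable weights. This makes "most ideal
geometry, least strain" the operative definition of the best match.

Within the engine, closed main loops are refined against the concrete
candidate donors: for each assignment of the TS-anchoring backbone roles,
ideal hydrogen-bond points (donor N plus the optimum distance along the
N–H direction) and the acceptor-neighbour direction solved from the
donor-angle cones (both cone intersections are tried) are added as extra
closure targets. This constraint-guided refinement is what turns a wide
closure manifold into the handful of geometrically ideal placements that
the ranking can then separate.

## 4. Repacking and the surrogate energy model

Design sites are all non-proline residues with any heavy atom within 7 Å
of the TS. The rotamer library is generated from standard staggered-χ
statistics (sp3 bonds at −60/60/180, planar groups at their common
orientations, syn-pentane combinations removed); a plain-text loader
accepts external libraries in the same per-residue χ-list format. Ser, Thr
and Tyr rotamers are expanded over hydroxyl-hydrogen torsions (120° grid by
default) because the hydroxyl proton position decides hydrogen bonds.

The energy model is a documented surrogate, authored for this package:
Lennard-Jones van der Waals with the repulsive branch linearized below 0.8
of the contact distance (all entries finite by construction), a directional
10–12 hydrogen-bond term (−2.5 PEU at 1.9 Å, scaled by the squared cosine
of the D–H···A deviation from linearity), and Coulomb electrostatics with a
distance-dependent dielectric (ε = 4r). Hydrogens carry a reduced van der
Waals radius (0.6 Å) so hydrogen-bonded H···acceptor contacts are not
punished as clashes. Charges are coarse CHARMM-style values stored on the
topology tables; TS models carry both CHARMM-style and PARSE-style charge
sets, selectable per run.

Optimization is exact: Goldstein dead-end elimination iterated to a
fixpoint (every eliminated rotamer is provably absent from the optimum),
then branch-and-bound depth-first search with an admissible lower bound.
No LP/MILP formulation is used — the exactness guarantee is the same, and
the random-instance oracle (exhaustive enumeration on small tables) checks
it on every run of the suite. Hydrogen bonds are detected at ≤ 3.3 Å
donor–acceptor (closed interval) and ≥ 120° D–H···A; the binding energy is
the bound-minus-separated difference at fixed conformations, which reduces
to the protein–TS interaction energy under the model's cutoff.

## 5. The synthetic fixtures: what they emulate, and what they do not

`generate_fixture()` builds the study system: it evaluates the motif's own
main-loop parameterization at planted torsions (χ from the rotamer
library, bounded parameters at their optima, orientation spins uniform),
reverse-builds the stabilizing side chains along their partners'
donor-hydrogen directions, materializes backbone anchors and oxyanion
donor segments around the solution (donors aimed at exactly the optimal
approach angle), and adds decoy residues in a 7.5–11 Å shell plus filler
segments farther out, with inter-segment heavy-atom contacts kept above
realistic packing distances (≥ 2.85–2.9 Å; hydrogen-bonded and
constraint-linked pairs excluded). Default conditions: ~30 residues, 4
decoy candidate sites, one fixture per seed, bitwise reproducible.

Planting χ at library rotamers and constrained parameters at optima
emulates a well-packed native site whose geometry the library can
represent — the situation in which recapitulation benchmarks are
meaningful. What fixtures deliberately do not model: Ramachandran-realistic
backbones (segments are idealized helical fragments), sequence diversity
(poly-alanine environment), crystallographic noise, waters, and metal
chemistry (excluded from scope). Passing the desk-scale tests therefore
demonstrates the correctness and calibration of the machinery on exactly
specified geometry, not performance on experimental structures; screening
real scaffolds additionally requires curated motif tolerances.

Problem sizes used by the suite and the acceptance script — 20 fixtures
for recovery, 5×21 paired trials for the closure harness, 100 random
instances for the rotamer-solver oracle, 1,000 Monte-Carlo conformations
per loop for the reach bound — are the package's chosen desk-scale study
conditions, small enough to run in a few minutes on a single core.

## 6. Degenerate inputs, tie-breaks and other numerical fine print

* Dihedral sign convention is the standard right-handed one, fixed by a
  test vector (`(0,0,0),(1,0,0),(1,1,0),(1,1,1)` → +90°); all periodic
  arithmetic funnels through one wrapping helper.
* Bond angles of exactly 0° or 180° are rejected as placement parameters
  (open interval), and collinear reference triples raise explicit
  degenerate-geometry errors.
* Altloc resolution keeps the highest occupancy, ties broken toward `A`
  then alphabetically; waters are dropped; only the first model of
  multi-model files is read.
* Ranking ties break by lower total repulsion, then lexicographic site
  ids; ranking is stable and idempotent.
* Reversed side-chain construction re-references branch atoms against
  placed path siblings with template-measured impropers, so ring closure
  and sp2 planarity are preserved for any value of the free torsions.
* Hydrogen placement needs the preceding residue's carbonyl carbon for the
  amide H; chain-terminal residues simply have none, and residues with
  missing side-chain heavy atoms are warned about and skipped as sites.

## 7. Known limitations

The energy model is a calibrated surrogate: sign patterns, rankings and
hydrogen-bond recovery are meaningful, absolute energies are not claims.
Scaffold backbones are rigid throughout (anchors never move), and no
sequence design is performed — matching assigns motif identities and
repacking optimizes conformations of existing identities only. The loop
builder supports linear side-chain paths with rigid-group completion
(covering Ser, Thr, Cys, Asp, Asn, Glu, Gln, His, Tyr, Lys and the other
standard types via the topology tables); exotic chemistry (metal
coordination, covalent intermediates) is out of scope. Match counts on
real libraries depend on curated tolerances; what the package promises is
the machinery, its exactness guarantees, and the planted-recovery behaviour
documented by its tests.
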