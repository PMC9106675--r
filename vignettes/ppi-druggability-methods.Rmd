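---
title: "Methods: pocket descriptors, druggability classification and drug-likeness"
author: "ppidrugg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pocket descriptors, druggability classification and drug-likeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppidrugg)
```

## The problem

Protein–protein interaction (PPI) interfaces are shallow, extended and
largely hydrophobic; whether a drug-like small molecule can engage them is
the central go/no-go question early in a discovery programme. The practical
instrument for that question is a *druggability score* computed from the
geometry and chemistry of the candidate pocket. This package implements a
ligand-seeded druggability workflow for PPI interfaces: curate a crystal
structure down to the inhibitor-bound chain, seed a single binding region
with a ligand (co-crystallised, or transferred from a reference complex by
superposition), measure the pocket, score it, classify the target, and in
parallel audit the drug-likeness of the target's known inhibitors.

## The score and its ingredients

The druggability score is the fixed linear combination

$$\mathrm{Dscore} = 0.094\sqrt{n} + 0.60\,e - 0.324\,p$$

where $n$ counts *site points*, $e \in [0,1]$ is the *enclosure factor* and
$p \ge 0$ the *hydrophilicity factor*. The score rewards large, buried,
hydrophobic pockets and penalises polar linings. `dscore()` evaluates the
equation exactly, with no clamping.

The three ingredients come from a grid/ray-casting engine
(`detect_site()`); the commercial tool that popularised this score keeps
its site-point algorithm proprietary, so the engine here is an open,
documented operationalisation of the three named quantities, validated by
properties (oracle equivalence, monotonicity, invariances, the no-site
state) rather than by numerical identity with any proprietary output on
deposited structures:

1. **Candidate grid.** An axis-aligned lattice at `grid_spacing` (default
   1.0 Å) covering the seed ligand's bounding box expanded by
   `region_margin` (6.0 Å). The lattice is anchored at the ligand centroid,
   so descriptors are exactly invariant to translation of the deposited
   frame. Points inside any protein heavy atom's Bondi van der Waals radius
   plus `probe_radius` (1.4 Å, a water-sized probe) are removed.
2. **Enclosure.** At each candidate point, rays are cast along a fixed,
   deterministic set of `ray_count` quasi-uniform directions (162 icosphere
   vertices by default); a direction is blocked if a protein atom's van der
   Waals sphere is intersected within `ray_length` (10 Å). The enclosure of
   the point is the blocked fraction. A point just above a flat wall sees
   slightly under half the sphere blocked, which is what makes the flat
   interface case work out below.
3. **Site points and clustering.** Candidate points with enclosure at
   least `enclosure_threshold` (0.5) are clustered by 26-neighbour lattice
   connectivity; the connected component closest to the ligand centroid is
   the site (ties: larger component, then lexicographic grid order). Then
   $n$ is the component size and $e$ its mean enclosure.
4. **Hydrophilicity.** Contacts are protein heavy atoms within
   `contact_cutoff` (4.0 Å) of any site point. $p$ is `k_p` times the
   polar-weighted contact fraction, where nitrogen and oxygen weigh 1,
   charged side-chain N/O (Arg/Lys/Asp/Glu/His termini) weigh 2 and carbon
   and sulfur weigh 0. The calibration constant `k_p = 1.6` maps the
   \[0, 1\] polar fraction onto the observed range of published per-target
   hydrophilicity medians (0.06–1.59); it is configurable and is the one
   deliberately phenomenological constant in the engine.
5. **No site detected (ND).** If fewer than `min_site_points` (5) points
   survive, the structure is reported as ND — the state a flat,
   featureless interface produces. ND records classify as *difficult*;
   where a plot or correlation needs a number they carry the surrogate 0,
   but medians never include surrogates. The floor of 5 sits safely below
   the smallest published per-target pocket ranges (8–9 site points).

### Classification

Two schemes are provided. The four-class PPI scheme
(`classify_ppi()`): Dscore ≥ 1.0 *very druggable*; ≥ 0.75 *druggable*;
≥ 0.5 *moderately druggable*; below that (or ND) *difficult*. All
boundaries are inclusive at the lower edge. The original three-class
scheme (`classify_halgren()`): < 0.8 *difficult*, ≥ 1.0 *very druggable*,
*druggable* between; the published rule says "greater than 1" and the
inclusive boundary here is a deliberate, documented choice for internal
consistency between schemes.

When a per-target class is derived from a summary table, the median Dscore
is rounded to two decimals first — the convention of the published
per-target tables, where an exact 0.99604 prints as 1.00 and is listed as
very druggable.

### Superposition of apo and peptide-bound forms

Structures without a co-crystallised ligand cannot seed a region by
themselves. `superpose_on_reference()` aligns the target and a
ligand-bound reference sequence (`global_align()`: Needleman–Wunsch with
affine gaps, BLOSUM62, gap open 10 / extend 1, a gap of length $k$ costing
$10 + k$; deterministic tie-breaking, match preferred over gap, then gap in
the first sequence), fits the Cα atoms of aligned pairs with the Kabsch
algorithm (`kabsch()`, proper rotation enforced via the determinant
correction), and applies the reference→target transform to the reference
ligand. The target's own coordinates are never touched; the ligand is
brought to the target, preserving each structure's native frame. At least
20 alignable Cα pairs are required; optional outlier trimming (2 SD, max 3
rounds, floor 20 pairs) is off by default. The alignment parameters are
community defaults, declared rather than inferred: the original workflow
used a commercial align/superpose feature whose settings are not public.

### Aggregation and flexibility analysis

`aggregate_target()` reports count, median, sample SD (n − 1), min and max
of Dscore and of the three descriptors, per structural form (apo,
protein/peptide-bound, ligand-bound) and overall. The even-count median is
the mean of the two middle values, which is how half-integer pocket sizes
(19.5, 32.5, 50.5) arise in per-form tables. ND records are counted but
excluded from statistics. `percent_reduction()` is
`round(100 · (ref − other)/ref)` — the arithmetic behind the reported
apo-vs-ligand-bound reductions (33% / 40% / 33%) and the protein-bound
reduction (20%). `pearson_r2()` supports both the drop-ND and the
ND-as-zero conventions, matching the published plotting convention.

## Drug-likeness

`ro5_violations()` counts the four Lipinski conditions (Mwt ≤ 500, LogP ≤
5, HBD ≤ 5, HBA ≤ 10); the strict rule passes at zero violations (a
documented flag relaxes this to ≤ 1, since the published audit table does
not state its convention explicitly). Ro5-1
(`is_druglike_ro5_minus_1()`) tolerates exactly one violation — the
relaxation proposed for PPI inhibitors, whose size and hydrophobicity
routinely break a single rule while retaining oral activity.
`qed_score()` maps the eight descriptors (Mwt, ALogP, HBA, HBD, PSA,
rotatable bonds, aromatic rings, structural alerts) through the published
asymmetric-double-sigmoid desirability functions and returns the weighted
geometric mean. The unweighted variant is the default because the source
analysis does not name its variant; the canonical published weights are
available via `weights = "canonical"`. Desirabilities are floored at
1e-6 purely as a numeric guard for the logarithm. The Rule-of-Four
profile (Mwt > 400, ALogP > 4, HBA > 4, rings > 4, all strict) is reported
as a descriptive fingerprint, not a filter. The module consumes property
tables, so no chemistry toolkit is needed at test time; computing
properties from SMILES/SDF is a pluggable backend concern.

## What the synthetic generator emulates — and what it does not

All tests run offline against generated fixtures, at three levels.

**Structures.** `make_cavity_structure()` builds a pseudo-protein slab of
single-atom residues on a cubic lattice (spacing 1.8 Å) with a pocket
carved into the top face: a sphere of accessible radius `radius` plus,
when `depth` exceeds `radius`, a cylindrical shaft to the surface
(hemispherical at `depth = radius`). The shaft design makes deepening
strictly nested, so the depth-monotonicity of $n$ is a meaningful
property; a plain descending sphere narrows its own mouth and shows
discretisation dips. Atoms carry real element symbols with Bondi radii, so
the engine treats fixtures and deposited structures identically. Lining
atoms become polar (alternating N/O) at `polar_fraction`; `rim_height`
adds occluding rings around the mouth; `depth = 0` is the flat,
ND-producing interface. The probe ligand is pinned at a fixed shallow
depth so the grid anchor is commensurate across depth series. One caveat
is inherent: substituting N/O for C changes the Bondi radius by ~0.15 Å,
so the polar variants of a cavity shift $n$ by a few points; the tests
bound this at the rigid-motion tolerance (15%) rather than demanding
identity.

**Apo/holo pairs.** `make_apo_holo_pair()` shares one atom and residue
roster between both members: the apo form refills a `closure` fraction of
the carved lattice sites (deepest first) by relocating the nearest lining
atoms into them. `closure = 0` reproduces the holo coordinates;
`closure = 1` restores the flat slab and yields ND — the apo-collapse
contrast reported for Bcl-xL and IL-2.

**Descriptor tables.** `make_descriptor_table()` draws per-structure
descriptor rows for a target: discretised log-normal for $n$ (strictly
positive, right-skewed, as the published ranges imply), clipped normals
for $e$ and $p$. The default sampler is stratified: draws sit at evenly
spaced quantiles with a seeded random assignment to structure identifiers,
ranks shared between $n$ and $e$ and reversed for $p$. This coupling
mirrors the reported relationships (druggability correlates strongly and
positively with pocket size and enclosure, inversely with hydrophilicity)
and keeps the sample medians faithful to the configured medians even at
small counts; independent pairing would deflate the per-structure score
median through a Jensen-type effect and misclassify boundary targets for
reasons unrelated to the code under test. An `iid` mode is available.
`emulate_reference_dataset()` instantiates the twelve published targets
(spreads derived from the published ranges as range/4 on the appropriate
scale, counts from the published per-form breakdown, the flat-interface
target as ND records).

One target deserves a note: the published Bcl-xL row is internally
inconsistent — its median descriptors (46, 0.71, 0.49) evaluate to a
Dscore of 0.90, not the published median score of 1.01, and its
ligand-bound median pocket size (140, for 16 of 24 structures) cannot
coexist with an overall median of 46. Any emulation anchored on the
per-target descriptor medians therefore reconstructs Bcl-xL as
*druggable* (0.90), one class below its published *very druggable*. The
test suite asserts exact class agreement for the eleven self-consistent
targets and pins Bcl-xL at the class its own parameters imply.

What the generator does **not** emulate: real protein geometry (secondary
structure, side chains, rotamers), crystallographic artefacts (missing
loops, alternate conformations beyond the parser's altloc handling),
induced fit beyond the radial refilling model, and any chemistry in the
property tables beyond the planted rule violations. Passing tests
therefore demonstrate that the engine measures what it claims to measure
on controlled geometry, and that the scoring, classification and audit
arithmetic reproduce the published aggregate values — not that the engine
numerically matches a proprietary descriptor stack on deposited PDB
entries.

## Numerical choices

* Bondi van der Waals radii; elements missing from the table fall back to
  carbon. Hydrogens are dropped at parse time — every quantity is
  heavy-atom based, and protonation is an upstream concern out of scope.
* Alternate locations resolve to the highest occupancy, first-listed on
  ties. Insertion codes are part of residue identity. Non-standard
  residues in ATOM records count as protein, preventing spurious
  stripping of selenomethionine and friends.
* Ray directions are icosphere vertex sets (12/42/162/642), sorted
  lexicographically: bit-identical descriptors for identical inputs, no
  randomness anywhere in the engine.
* Cluster ties break to the larger component, then lexicographic grid
  order; chain-selection ties break by chain label order. Every tie-break
  in the package is deterministic and documented.
* Rigid-motion tolerance: descriptors are exactly invariant under
  translation (anchored grid); under rotation the lattice re-samples the
  pocket, and at the default operating point (1 Å grid, 162 rays,
  radius-4 Å cavity) 20 random rigid motions stay within |Δn|/n ≤ 0.15
  and |Δe| ≤ 0.05. Coarser settings (42 rays) exceed these bounds on
  small pockets, which is why the stability suites run at full
  resolution.
* The ligand-proximal chain is chosen by minimum heavy-atom distance with
  a 5.0 Å contact cutoff, configurable. Multiple ligand copies without a
  chain disambiguation raise an error rather than guessing, since the
  original curation does not state a rule.

## Problem sizes

The test fixtures are sized for fast, deterministic runs: slabs of
roughly 600 atoms (half-width 9 Å) with 42-ray enclosure for
oracle-equivalence and monotonicity checks, and the full 2,400-atom,
162-ray operating point for the stability suites and worked examples. The
dataset emulation uses the published 320-structure layout across twelve
targets. These sizes are the package's validation choices; the engine
itself has no size limits beyond memory, and a realistic single-chain
structure with a posed ligand processes in about a second.

## Known limitations

* The descriptor engine is a surrogate: its absolute $n$, $e$, $p$ are
  calibrated to be *commensurate* with the published per-target medians
  (via `k_p` and the defaults above), not to reproduce any proprietary
  engine's per-structure values. Synthetic pockets score systematically
  high on enclosure because lattice walls are denser than folded protein.
* Hydrophilicity is a contact-count ratio, not an energy; pockets whose
  polarity comes from backbone carbonyls in otherwise apolar residues are
  under-weighted relative to an energy-based philic potential.
* The sequence alignment is global; multi-domain targets with large
  insertions are better served by aligning the relevant domain only.
* Drug-likeness audits take property tables as given; no standardisation
  of tautomers, salts or charge states is attempted.
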