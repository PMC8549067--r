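---
title: "petworld: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petworld: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and algorithms behind `petworld`, the
choices made where the design was genuinely open, and what the test suite
does and does not demonstrate.

## The pet representation

A pet molecule is a 1/10-linear-scale approximation of an all-atom
structure made of spherical pseudo-atoms drawn from twelve artificial
elements (`O1`…`O9`, `OA`, `OB`, `OC`; vdW radius of element *k* is
*k*/10 Å). Working at 1/10 scale keeps coordinates in ordinary PDB/mmCIF
numeric ranges while cutting the atom count to a few percent, which makes
packing simulations and collision tests of mesoscale assemblies tractable.
Every pet object keeps a backup of its all-atom source, so expansion is an
exact restoration plus a ×10 rescaling of the inter-copy translations.

## Two-pass shrinking on a density grid

The all-atom molecule, scaled to 1/10, is rasterised on a cubic grid with
cube side 2^(13+n) fm, n = 1, 2, 3 for a smallest pet radius of 0.1, 0.2 or
0.3 Å (so 0.16384, 0.32768 or 0.65536 Å). A grid point is *inside* when it
lies within the scaled vdW radius of at least one atom — the simplest
density definition consistent with surface tracing. The grid box carries a
margin of (largest pet radius + 2 spacings) so probes near the surface
never fall off the grid.

For a probe of radius *r* centred on a grid point we count

* `InnerCount` — probe points flagged inside the molecule,
* `PetPoints`  — all points in the probe (distance ≤ *r*),
* `DoubleCount` — probe points already covered by accepted pet atoms,
* `OuterCount` / `OuterPoints` — the same for the *two-point-wide shell*
  (*r* < d ≤ *r* + 2·spacing).

The per-pass scores are built from these counts with weights
W_IC = 3.5 and W_DC = 1.5:

* pass 1 (surface): `W_IC · InnerCount · (OuterPoints − OuterCount) /
  OuterPoints − W_DC · DoubleCount`
* pass 2 (hole filling): `InnerCount − W_DC · DoubleCount`

These forms are this package's design, pinned by the constraints the
method's description fixes: the pass-2 score is maximal and equal to
`PetPoints` exactly when the probe is full and uncovered; a fully buried
probe has `OuterCount = OuterPoints` and scores ≤ 0 in pass 1, so pass 1
can only accept surface-touching probes and the interior is left to
pass 2. The acceptance thresholds follow the stated identities: minimum
pass-1 score = maximum pass-2 score = `PetPoints(i)`; minimum pass-2 score
of radius *i* = `PetPoints(i−1)/2` of the next smaller radius in use, and
`PetPoints(i)/2` for the smallest.

Placement processes radii in descending order. The candidate table is
sorted by (score desc, linear grid index asc) — the index tie-break makes
placement deterministic. Entries are rescored lazily on pop against the
current coverage: dropped below the pass minimum, re-inserted at their new
rank when demoted, otherwise accepted, flagging every enclosed grid point
as covered. Scoring of the whole grid is done two ways: a vectorised
whole-array shift accumulation (the default) and an incremental X-sweep
that adds the offsets entering the probe and subtracts those leaving it;
both produce identical integer counts, and the equivalence is asserted in
the tests over all twelve radii and both passes.

Bonding joins pet atoms closer than the sum of their radii, bonds residual
loners to their nearest atom, and connects remaining components through
the shortest inter-component contact until one component remains.

## Pet nucleic acids

The geometry table (`na_geometry()`) stores real-world Å and degrees for
B-DNA and A-RNA (rise, twist, C1\*-axis distance, sequential/paired
C1\*–C1\* distances, the C1\* angle/dihedral set and backbone torsion
defaults); pet builders multiply distances by 0.1.

`build_pet_ss()` lays out one 0.5 Å pet atom per nucleotide with a seeded
self-avoiding walk: step length = sequential C1\*–C1\* distance / 10,
minimum non-bonded separation 0.4 Å (pet), and bend angles drawn around
the equilibrium C1\*–C1\*–C1\* angle (σ = 10°) with uniform azimuths. The
conformation is deliberately random — a realistic fold is expected to
emerge from pet-world dynamics — but the local stiffness mirrors a real
C1\* chain, which also keeps consecutive nucleotides in reach of backbone
closure during expansion. `build_pet_ds()` places one 1.2 Å main atom per
three base pairs on the axis (spacing 3·rise/10) plus a 0.1 Å helper
1.2 Å off-axis, rotated by 3·twist between consecutive mains.

Double-strand detection screens consecutive strands (split at chain or
residue-number discontinuities) that have equal length, run anti-parallel
and keep all paired C1\* pairs closer than 1.2 Å at pet scale. Note that
this printed criterion fires on B-form duplexes (paired distance
10.8 Å → 1.08 Å pet) but not on ideal A-form duplexes, whose paired
distance (12.68 Å → 1.268 Å pet) exceeds the threshold; the package
implements the rule as stated rather than widening it.

### Expansion to all-atom

Each single-strand pet atom is replaced by a template nucleotide. The
local frame at C1\*(i) uses X = sum of unit vectors to the neighbouring
C1\*s, Z = X × v_next, Y = Z × X; chain termini use the single neighbour
vector. The base anchors N3 and C6 (present in all five bases) are
computed from their template coordinates in this frame and the template is
superposed rigidly on C1\*/N3/C6 (a three-point Kabsch fit, exact by
construction). For nucleotides inside paired stems the local C1\* triplet
is first idealised by fitting a standard three-base-pair fragment to the
six C1\* positions. The shipped templates are *synthetic minimal*
nucleotides built in code (ribose/backbone plus a planar base ring) with
standard bond lengths but idealised ring geometry; they are drop-in
replaceable by crystallographic templates.

Backbone O3\*(i−1)–P(i) gaps are closed by cyclic coordinate descent over
the three backbone torsions C3\*–C4\*–C5\*–O5\*, C4\*–C5\*–O5\*–P and
C5\*–O5\*–P–O3\*(prev): each torsion's rotation angle is solved in closed
form on the circle the moving atom travels, targeting the 1.6 Å bond
length; a guard accepts a rotation only if it does not worsen the gap, so
the gap is non-increasing every sweep. Stopping: 0.05 Å tolerance or 50
sweeps. Degenerate axes (coincident atoms, moving point on the axis) are
skipped for the sweep. On 50-nt random coils, all junctions close below
2 Å in the test suite.

Double-strand expansion rebuilds a linear helix from the geometry table,
bends it along the ×10 main-atom trace (linear axis interpolation between
mains, each main anchoring the middle base pair of its triplet) and phases
the twist from the helper directions, then places nucleotides on both
strands with the frame method.

## Membranes

Transmembrane detection works per ungapped secondary-structure run (split
at chain boundaries): helices 12–29 residues with more than 4 exposed
hydrophobics, strands 7–14 with more than 3. *Exposed* means side-chain
SASA above 20 % of the residue maximum; SASA is computed by a Shrake–Rupley
sampler (probe 1.4 Å, 96 Fibonacci points per atom) and the maxima are the
published theoretical Gly-X-Gly values. A segment is rejected outright if
it contains a strongly polar residue (Asn, Gln, Lys, Arg, Asp, Glu), and
must present a side — a 120° sector around the regression axis for
helices, one alternating face for strands — on which every exposed residue
is hydrophobic. Orientation sign-corrects the segment axes against the
first one, sums them, and rotates the sum onto +Z; the hydrophobic band is
then located by scanning a 30 Å slab in 1 Å steps, with exposed
hydrophobics in TM segments counting five-fold. The slab thickness is this
package's choice (a typical bilayer core).

Pet membrane blocks place 1.2 Å pet atoms on a hexagonal lattice (spacing
2.4 Å pet, so neighbours touch) in two layers, clipped to a rectangle,
60°/120° rhombus, or equilateral triangle (half rhombus); bonds connect
touching in-layer neighbours and nearest inter-layer partners. Bilayer
classification finds the membrane normal as the principal axis along which
the headgroup atoms split into two leaflets (largest mid-gap; below 12 Å
the object is rejected as a monolayer), then compares the in-plane convex
hull with its minimum-area enclosing rectangle: fill fraction ≈ 1
rectangle, ≈ 2/3 rhombus, ≈ 1/2 triangle. Extents are corrected by one
lipid lattice spacing for the half-cell hull inset. The all-atom MD steps
of membrane-block preparation (lipid mutation, solvated equilibration) are
out of scope; blocks here are geometric.

## Tessellation

Adjacent face pairs are scored against the ideal rhombus — two equilateral
triangles joined on an edge, reference area taken over the mesh's mean
edge length. The deviation is the product of the relative differences in
area and in the four corner angles, and the score is its reciprocal:

    score = 1 / [ (1 + |A − A0|/A0) · Π_k (1 + |θ_k − θ_k,ideal|/θ_k,ideal) ]

so ideal rhombi of the reference area score 1 and the score strictly
decreases as any corner angle or the area deviates. The exact algebraic
form is this package's design; the maximality/ordering properties above
are the contract.

The triangle with the highest sum of its three pair scores seeds three
greedy runs (one per candidate rhombus); each run pops the best frontier
rhombus, skips used faces, and pushes the neighbours across the accepted
rhombus's outer edges; the run with the highest total score wins. Because
the construction stops only "when no rhombus can be placed", the greedy
pairing is then completed by alternating-path augmentation over the
face-pairing graph (with a local unmatch-and-retry escape for the rare
odd-cycle blocks); on icospheres this drives the triangular hole count to
zero at every subdivision level. Starting-triangle ties break by index
order. Block placement orders rhombi by score, shuffles the top 90 % with
a seeded Fisher–Yates permutation, places protein-carrying blocks with a
pet-atom collision test (broad phase cell = 2 × largest pet radius), and
fills everything left with empty blocks. Blocks map onto mesh rhombi by a
least-squares 2D→3D affine fit of the ideal corners (mesh rhombi on curved
surfaces are slightly non-planar, so the fit is least-squares rather than
exact); the out-of-plane axis maps to the target plane normal at unit
scale.

## Force field

AMBER functional forms with the pet defaults: bond k = 575 kcal/(mol Å²)
(E = k(r − r0)²), angle k = 300 kcal/(mol rad²), dihedral
(pk/idiv)(1 + cos(pn·φ − phase)) with pk = 5, pn = 1, idiv = 1 and
phase = equilibrium + π (zero energy at the equilibrium), mass 8 u for
every type, charge = 0.1 × summed source charges, cutoff 3 Å.

Equilibria come from the construction coordinates for B-factor-0 atoms and
from the geometry table for sequence-built atoms (distances ×0.1):
sequential bonds 0.495/0.533 Å, pairing bonds 1.08/1.268 Å, the C1\*
angle/dihedral set, main–main bonds 3·rise/10, helper bonds 1.2 Å. The
double-strand axis avoids the 180° angle singularity with two 90°
helper–main–main angles, and helper–main–main–helper dihedrals equal
3 × twist.

Exclusion rules: no angle terms inside 3-rings; inside each 4-ring only
the two *neighbouring* terms are kept — implemented as the terms centred
on the lowest-index ring atom and its lowest-index ring neighbour (the
paper leaves which two open); angles with equilibria outside (20°, 160°)
are excluded along with dihedrals over excluded triplets; angles with a
degenerate (zero-length) arm — possible when two pet atoms share a centre
— are excluded likewise. Dihedrals follow the minimal recipe exactly: a
term for A–B–C–D only when A has fewer than four bonds and B exactly two.

Nonbonded: 1-2 and 1-3 pairs are excluded; 1-4 pairs are *not* scaled,
since exclusion is defined through bonds alone in this model. vdW uses a
12-6 form with rmin = r_i + r_j and a single well depth of 0.05 kcal/mol
for all pet pairs (the model is repulsion-dominated and no well depths are
prescribed; the value is configurable). Coulomb is plain and truncated at
the cutoff with dielectric 1 — long-range electrostatics and implicit
solvent are out of scope.

Minimization is steepest descent with a backtracking line search (energy
non-increasing at every accepted step). Dynamics is velocity-Verlet with
impulse multiple time stepping: bonded forces at 0.5 fs, nonbonded kicks
at 1 fs, seeded Maxwell–Boltzmann initial velocities (energy unit
conversion 1 kcal/mol = 4.184 × 10⁻⁴ u Å²/fs²). A practical stability
note: angle terms between pet atoms bonded at very short distances
(≲ 0.3 Å arms, which occur in densely shrunk cores) translate the angular
stiffness into very high Cartesian frequencies; the 0.5 fs bonded step is
comfortable for pet nucleic acids and membrane blocks (NVE drift well
under 1 % of the kinetic energy in the tests) but structures fresh from
the builders should be energy-minimized before dynamics.

## Reduced level-of-detail meshes

Density mapping: the signed surface distance d (negative inside) is
clamped to [−L, L] (L = one grid cube) and mapped linearly to a byte,
ρ = ⌊255(L − d)/(2L) + 0.5⌋, so −L → 255, 0 → 128, +L → 0; isosurfaces are
extracted at 128. Grids are forced to even dimensions so 8-cell averaging
conserves the mean exactly; colours downsample by majority vote.

Secondary-structure styles build a Catmull–Rom spline through the Cα atoms
of each ungapped stretch (strand control points smoothed over a 4-residue
window), subdivided into four segments between residues, each capped by
cut planes normal to the spline tangent with parallel-transported in-plane
frames. Cross sections are circles (tube r = 0.75 Å, helix cylinder
r = 2.3 Å) or p4-symmetric octagons (ribbon/arrow, width 1.5 Å, thickness
0.4 Å, arrows tapering over the final residue) — visualization constants,
all configurable. The surface distance estimator projects the point onto
both cut planes, finds in each the piercing point of the ray normal to the
nearest cross-section edge, and returns the signed distance to the line
joining the two piercing points; this is exact for untapered circular
segments and within ~10 % for tapered ones. Each segment is rasterised by
flood fill seeded at the grid point nearest the segment start, visiting
neighbours while the density is positive; overlaps keep the maximum
density and its colour, which makes the result independent of segment
processing order, and an auxiliary grid records the owning segment.

Isosurfaces are extracted by marching cubes with six-tetrahedron cell
decomposition: each cube splits into six tetrahedra whose 14 sign cases
are unambiguous, vertices interpolate linearly on crossing edges and are
welded per edge, so closed blobs yield watertight meshes (Euler
characteristic 2 in the tests). Vertex colours inherit from the denser
edge endpoint. Default spacing for the finest level is 1.5 Å, with each
coarser level doubling it.

## Synthetic data

The generators provide deterministic, seeded inputs: globular atom clouds
(jittered cubic lattice at 0.09 atoms/Å³ with H/C/N/O Bondi radii — the
protein-like packing regime), ideal α-helix bundles (rise 1.5 Å/residue,
100°/residue, pseudo side-chain centroids, per-helix chains and H labels),
pseudo-lipid bilayers (three-atom lipids, headgroups at ±20 Å, lattice
spacing 8 Å, POPC residue names), icospheres (20·4^s faces) and random
sequences. They emulate the *geometry* the algorithms consume — packing
density, helix dimensions, leaflet separation, mesh regularity — but not
real chemistry: no rotamers, no sequence-dependent helix parameters, no
lipid conformations, no experimental noise. Passing tests therefore
demonstrate algorithmic correctness on well-posed geometry, not biological
accuracy on crystal structures.

Problem sizes in the test and acceptance runs are chosen for desk-scale
turnaround: 5000-atom clouds (five seeds) for the compression figure,
≤ 20³ score-equivalence grids, 50-nt coils for closure statistics,
icospheres to subdivision 3 (1280 faces), 12-atom chains with a few
hundred fs of NVE dynamics.

## Known limitations

* The exact printed algebra of the pass scores and the rhombus score is
  not recoverable from the source text; the implemented forms satisfy all
  stated constraints but are not guaranteed term-for-term identical.
* The double-strand distance criterion (1.2 Å pet) does not fire on ideal
  A-form duplexes (see above).
* Nucleotide templates are idealised stand-ins; expanded structures are
  geometrically consistent but not stereochemically refined.
* Genome assembly joins fragments by rigid translation of the binder
  fragments; no excluded-volume optimisation beyond the walk's 0.4 Å
  floor (pet scale) is attempted, and overlapping binding sites resolve
  leftmost-first with a warning.
* Membrane blocks are geometric; no lipid-level equilibration, curvature
  bending, or leaflet asymmetry.
* The integrator has no thermostats beyond seeded initial velocities and
  is a reference implementation, not a performance MD engine.
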