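---
title: "Modeling symmetric assemblies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling symmetric assemblies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symmdef)
```

## The problem

Homomeric protein assemblies — rings, dihedral stacks, fibers, crystals —
are built from chemically identical subunits related by symmetry
operations. Symmetry makes very large systems computationally tractable:
instead of 6(N−1) rigid-body degrees of freedom for N subunits, a
symmetric system typically has 3–6, and instead of O(N²) subunit-pair
interactions only the interactions touching one *master* subunit need to
be evaluated. `symmdef` implements that machinery end to end: a text
format describing the symmetry (the symmetry definition file, SDF),
kinematics that propagate every master move to the slave subunits,
weighted energy evaluation from an explicit subset, symmetric side-chain
packing, analytic gradient minimization, and a rigid-body docking
protocol.

## The symmetry definition file

An SDF declares (i) virtual coordinate frames — non-physical "virtual
residues" that anchor subunits — either explicitly (`xyz` lines: origin
plus x/y unit axes) or implicitly (a transform recipe, e.g. `rot Rz 2`);
(ii) a jump tree connecting a root, the frames, and the subunit
attachment points; (iii) clone groups of jumps that share one 6-vector of
rigid-body values (three translations in Å, three rotations in degrees);
(iv) `set_dof` lines naming which components may move, their initial
values and sampling ranges; and (v) an energy line such as

```
E = 2*VRT0_base + 1*(VRT0_base:VRT1_base)
```

reading: the total system energy is twice the master subunit's internal
energy plus once the master–slave interface energy. Angles are degrees in
files and at every exported interface; radians are internal only.

Two conventions are worth noting because the format's full grammar is not
standardized anywhere we could adopt it from: multipliers are parsed as
reals (integer in every printed example, but real weights cost nothing
and support averaged lattice terms), and frame axes within 1e-3 of
orthonormal are re-orthonormalized by Gram–Schmidt — files printed with 7
decimals are not exactly orthonormal and must not be rejected. Clone
weights ride on `set_jump_group` entries as `JUMP=weight` suffixes. A
`full_system_frames` line lets a definition carry all N frames while
attaching only S < N subunits, so subsystem definitions can still be
expanded to the complete assembly without out-of-band knowledge.

## Kinematics

Every frame has a reference placement from the SDF; its current placement
composes the parent's placement, the reference relative transform, and
the clone group's jump 6-vector applied **in the frame's own local
axes** — the property that makes one shared value move every clone
identically and preserves the point group by construction. The jump
convention (rotation about local x, then y, then z, then translation
along the local axes) is a documented choice of this package; no
published convention exists for the composition order, so numerical
comparison against other implementations must account for it.

The master subunit's atom coordinates are the single source of truth;
slave coordinates are always derived through the frame placements, never
stored. Torsion changes rotate the atoms on the far side of the bond
(relative to the anchor residue) and reach every subunit through the same
derivation, so the slave-consistency invariant
`slave_k == T_k(master)` holds to machine precision after any sequence of
moves — the property the test suite asserts at 1e-9 Å.

Fully randomizable orientations (all three angles allowed with 0:360
ranges) are drawn uniformly from SO(3) by the uniform-quaternion method
and decomposed into the jump's Euler angles; drawing three independent
uniform Euler angles instead would oversample the poles, which is visible
in the rotation-angle density test.

## Weighted energy evaluation

The energy function here is a deliberately simple, fully documented
stand-in: a 6-12 van der Waals form (well depth 0.25 energy units at 4 Å)
with linear softening below 2.4 Å and a C1 cubic switch from 8 Å to
exactly zero at the 10 Å cutoff, plus a constant one-body reference of
−0.5 per residue, plus optional harmonic coordinate tethers as the
whole-structure class. The scientific content being exercised is the
weighting and truncation machinery, which is agnostic to the functional
form; what the form must provide is (a) exact zero beyond a finite
cutoff, which makes explicit-subunit truncation *exact* rather than
approximate, and (b) a continuous first derivative, without which the
analytic-versus-finite-difference gradient contract cannot be met at the
switch boundaries. The C1 switch (rather than a plain linear taper) is a
design choice made for (b).

Interface multipliers are symmetry orbit sizes: for C4, the six subunit
pairs fall into an adjacent orbit of four and a diagonal orbit of two, so
`E = 4*E(A) + 4*E(AB) + 2*E(AC)`. One representative term is written per
orbit; the master's *other* adjacent neighbor (A–D) then carries weight
zero, because its energy is already counted four times through the A–B
term. Weight-zero edges are therefore the normal, exact configuration,
not an error. The package's central design property — symmetric scoring
of a point-symmetric complex equals brute-force asymmetric scoring of the
full expansion — is asserted to 1e-6 relative over hundreds of
randomized configurations, and truncation soundness is asserted exactly
on a C17 ring whose skip-one neighbors sit outside the cutoff (three
explicit subunits suffice).

Whole-structure terms are computed over the explicit complex, unscaled,
which is what makes the point-symmetry equality above hold; for lattice
systems (helical, crystal), where the explicit subset truncates an
infinite system, the energy line is lattice-normalized instead (per-N
one-sided interfaces for fibers; twice the per-subunit energy for
crystals) and the full-expansion oracle is deliberately undefined.

## Symmetric packing

A packer state `s_i` at master position i stands for the whole collection
of its symmetric copies. With `w_c` the intra weight and `w_k` the
master/subunit-k interface weight, node energies collect the
`w_c`-weighted own-background terms, the `w_k`-weighted cross-background
terms in both directions, and the interactions of a rotamer with its own
clones; edge energies collect all clone pairings of two positions onto
the one master edge. Subunits with `w_k = 0` are skipped entirely. The
identity that justifies these equations — graph energy of any assignment
equals the plain asymmetric packer energy of the replicated assignment on
the expanded complex — is asserted exhaustively (all 27 assignments of a
3-position × 3-state C2 system) rather than spot-checked.

The bundled rotamer library is minimal by design: canonical chi1 bins at
±60/180 degrees plus the input state, on a two-atom (CB–CG) side chain.
The annealer is geometric-schedule Metropolis (T from 100 to 0.3 over 200
steps per state), deterministic per seed, with ties resolved to the
lowest state index; on small graphs it reproduces the exhaustive optimum
in ≥95 of 100 seeded runs and can never undercut it.

## Minimization

All rigid-body partials are exact chain-rule derivatives through the
placement recursion: the derivative of every frame placement (a 4×4
matrix) is propagated down the jump tree, then into per-atom position
derivatives. Two consequences matter:

* **Cloned-jump weights.** The m-th clone of a lattice jump enters the
  recursion m times, so an interaction spanning m rise copies
  automatically contributes m times the one-copy derivative — the
  analytic distance derivative between a master and the subunit two rise
  steps away is exactly 2 Å per Å of rise. `cloned_jump_chain()` exposes
  this decomposition per interface, with the stored integer clone
  weights, and its totals reproduce the gradient entries identically.
  Because the lattice energy line is one-sided, upstream interfaces carry
  weight zero and rise gradients accumulate in one direction only —
  otherwise the upstream and downstream contributions of a symmetric pair
  potential would cancel at every spacing.

* **Correction gradients.** When a whole-structure energy applies
  *asymmetrically* (a tether to fixed global targets), slave gradients
  rotated into the master are correct for the inter-subunit jumps but
  wrong for a movable whole-system jump, where the unrotated gradients
  must be used. `corrected_gradient()` implements the literal recipe —
  rotate and accumulate per subunit for the attachment dofs; at the root
  virtual, subtract the rotated and add the unrotated accumulations,
  recording the difference in a correction ledger — as a second,
  independent route, and the test suite requires it to agree both with
  the generic chain rule and with central finite differences to 1e-4
  relative over dozens of random tether placements.

Finite-difference validation is a public operation
(`check_derivatives()`), not just a test, because derivative bookkeeping
is the hardest content here. The descent itself is limited-memory
quasi-Newton (L-BFGS-B via `stats::optim`) with the analytic gradient and
box constraints from non-circular dof ranges; backbone torsions are not
part of the default minimization surface (rigid-body minimization is the
default protocol step), which keeps the default acceptance surface fast.

## Docking and fixtures

Docking follows the standard symmetric assembly recipe: uniform random
orientation, slide moves along the translational dofs until atomic
contact (default criterion: any inter-subunit atom pair under 4.5 Å, step
0.5 Å, backed off one step; D-type systems slide both directions in
declaration order), a rigid-body Metropolis search under a
residue-centroid low-resolution score (contact reward in the 8–12 Å band,
quadratic clash penalty below 4 Å, temperature 2.0), and all-atom
Monte-Carlo-minimization refinement (rigid perturbation of 2 Å / 25° +
packing + minimization per cycle, Metropolis-accepted at temperature 1).
Each output model runs three independent low-resolution trajectories and
refines the best: the low-resolution contact score and the all-atom
optimum do not rank alternative packings identically on toy subunits, so
a model's refinement deserves more than one basin candidate. The slide
step, contact threshold, Monte Carlo temperatures, start counts and
perturbation magnitudes are this package's documented defaults, chosen
for the bundled fixtures; none is claimed to match any other
implementation. Every model is seed-reproducible and exactly symmetric.

The synthetic fixtures emulate the canonical scenarios: contacting
C2/C3/C4 rings, a C17 ring spaced so only nearest neighbors interact
(ring radius set for 9.5 Å adjacent anchor spacing: nearest-neighbor
Cα contacts at ~4.7 Å, skip-one at ~12.3 Å), a D2 stack with ring and
separation dofs, a 5-subunit fiber (twist 100°, rise 4.8 Å, radius 0 so
anchor separations are purely axial and the clone-span derivatives are
exactly integer), and a P1 crystal cell sized from the molecule's Cα
bounding box plus an 8 Å face gap (inside the cutoff, while the
8√2 ≈ 11.3 Å edge-diagonal gap is outside), giving the 7-subunit
face-neighbor shell. Subunits are ideal-geometry polyalanine built from
internal coordinates (φ/ψ −57/−47 helices; a 70/−130 two-residue turn for
the two-helix hairpin used in docking, chosen so the packed hairpin is
sterically relaxed). These toys exercise the symmetry machinery fully,
but they are not real proteins: passing tests demonstrate correctness of
the kinematic, scoring and derivative bookkeeping, not predictive
accuracy of the simplified energy on real assemblies.

The docking self-recovery fixture defines its "designed" C2 complex as
the global optimum of the documented score over the symmetric dof space,
located by a deterministic 48-start slide+minimize sweep; twenty
independently seeded docking runs must then re-find that basin within 2 Å
symmetric RMSD at least once. Symmetric RMSD minimizes the Cα RMSD over
symmetry-consistent chain relabelings (cyclic rotations and reversed ring
order for Cn, the dihedral permutations for Dn), each with its own
optimal superposition — exact and cheap for Cn/Dn; exotic user-supplied
groups would need their own permutation set.

## Degenerate inputs and numerical choices

Orthonormality tolerance 1e-3 with Gram–Schmidt repair (7-decimal files);
rotation-angle extraction at 180° uses the symmetric part of the rotation
matrix (the skew part vanishes); the symmetrization heuristic rounds the
fitted rotation to 360/n with n clamped to [2, 60] and warns beyond 10°
deviation or 2 Å residual rather than refusing — a very asymmetric input
produces a faithful warning and a far-away symmetric system, which is
reported, not hidden. Cyclic-symmetry axis location solves (I−R)c = t by
pseudoinverse (the axis direction is the null space). Sequence-adjacent
residue pairs (|i−j| < 2) are excluded from the nonbonded sums in every
code path, symmetric and asymmetric alike. A subunit at radius zero gets
an arbitrary perpendicular frame x-axis; a fold < 1, a dn with odd
subunit count, an unsupported spacegroup, and a dof set on an undeclared
jump are all hard errors with the offending name in the message.

## Known limitations

Tetrahedral/octahedral/icosahedral point groups are supported only
through user-supplied explicit frames (no automatic detection);
2D wallpaper groups are out of scope; crystal cells are fixed during
simulation (no cell-parameter minimization) and only five spacegroups
ship built-in operator tables; nonpolar helical symmetry (a D group per
rung) is not understood by the helical fitter; the energy function is a
toy and the rotamer library is one chi angle deep. Whole-structure
energies over lattice systems are computed over the explicit subset and
should be interpreted with care — there is no obviously correct
normalization for a truncated infinite system, so none is invented.

## Problem sizes

The test and acceptance workloads use 6–20-residue polyalanine subunits,
rings up to C38 (three explicit), 100-draw scoring equivalence sweeps per
point-group fixture, 50 random tether placements for the correction
gradients, 100 seeded annealing runs, and 20-seed docking recovery with
150 low-resolution moves and 14 refinement cycles per model — sizes
chosen so the full suite exercises every contract in a few minutes on a
single core while remaining far above the scale where the tested
identities could hold by accident.
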