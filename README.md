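# symmdef

Modeling arbitrarily symmetric macromolecular assemblies in R: symmetry
definition files, virtual-frame kinematics with master/slave propagation,
weighted interface-multiplicity energy evaluation, symmetric side-chain
packing, analytic gradient minimization (including cloned-jump weights
for lattice symmetry and correction gradients for asymmetric
whole-structure energies), and symmetric rigid-body docking.

## Who this is for

Structural modelers working with homomeric assemblies — cyclic and
dihedral point groups, helical fibers, crystal lattices — who need the
bookkeeping that makes symmetric simulation cheap and exact: sample only
the symmetric degrees of freedom, explicitly model only the subunits the
master interacts with, and still recover the energy and gradients of the
entire system.

## The core idea

A symmetric system is declared by a **symmetry definition file (SDF)**:
virtual coordinate frames related by the symmetry group, a jump tree with
cloned rigid-body degrees of freedom, and an energy line whose
multipliers are the interface orbit sizes. For a C4 ring with subunits
A–D, the six interfaces fall into two orbits (adjacent ×4, diagonal ×2),
so the total energy is reconstructed from the master subunit alone:

    E = 4*E(A) + 4*E(AB) + 2*E(AC)

Every move is applied to the master and replicated into each slave's own
reference frame, so the point group is preserved by construction, the
number of rigid-body dofs drops from 6(N−1) to at most 6, and — the
property the test suite leans on — symmetric scoring of a point-symmetric
complex equals brute-force scoring of the full expansion to 1e-6
relative. For lattice systems, derivatives traversing m copies of a
cloned jump are scaled by m (the rise derivative two subunits down a
fiber is exactly 2), and asymmetrically applied whole-structure energies
get the rotate/correct gradient treatment with an explicit correction
ledger.

Energies use a documented simplified potential (softened 6-12 van der
Waals with a C1 switch to zero at 10 Å, constant per-residue reference,
optional harmonic tethers) — the symmetry machinery, not the force field,
is the subject here.

## Worked example

```r
library(symmdef)

# a de novo C2 definition: subunits start at (50,0,0) and (-50,0,0)
sd <- generate_point_sdf("cn", 2)
sub <- make_toy_subunit(16, "hairpin")       # two-helix toy subunit
conf <- build_conformation(sd, sub)
ef <- energy_function()

conf <- random_orientation(conf, "BASEJUMP", seed = 9005)
conf <- slide_into_contact(conf, ef)          # translate until contact
conf <- set_jump_dof(conf, "BASEJUMP", "x",   # back off slightly
                     get_jump_dof(conf, "BASEJUMP", "x") + 0.6)
score(conf, ef)$total
#> [1] -22.07179
score_full_oracle(conf, ef)                   # brute-force expansion agrees
#> [1] -22.07179

check_derivatives(conf, ef)[, c("dof", "analytic", "numeric", "abs_error")]
#>                dof     analytic      numeric    abs_error
#>        BASEGROUP:x  2.516344600  2.516344581 1.896058e-08
#>  BASEGROUP:angle_x -0.005167022 -0.005166935 8.676105e-08
#>  BASEGROUP:angle_y  0.024448398  0.024448367 3.044716e-08
#>  BASEGROUP:angle_z  0.033592069  0.033592058 1.124101e-08

res <- minimize(conf, ef)                     # analytic-gradient descent
c(res$initial_score, res$final_score)
#> [1] -22.07179 -58.44070
```

The score is the total dimer energy reconstructed from the master subunit
(twice the internal energy plus the unique master-slave interface); the
oracle is the same quantity summed over every atom pair of the expanded
dimer with no symmetry shortcut. The derivative table compares the
analytic partials of the four allowed rigid-body dofs with central finite
differences; minimization then descends those gradients to a packed dimer.

A command-line entry point mirroring the classic symmetry scripts
(`make-symmdef`, `make-symmdef-denovo`, `score`, `pack`, `minimize`,
`dock`, `fixtures`) is installed at

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/symmdef-tool.R", package="symmdef"))')" \
    make-symmdef-denovo -symm_type cn -nsub 2 > C2.symm
```

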