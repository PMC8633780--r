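---
title: "Constraint-network rigidity, elastic network modes and geometric simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-network rigidity, elastic network modes and geometric simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexrig)
```

`flexrig` answers three questions about a protein crystal structure without
any force field: which parts are rigid, along which directions the structure
moves most easily, and how far it can actually move along those directions
while keeping its bonding and steric geometry. This vignette is the
package's own account of the models behind each answer, the parameters that
matter, and the limits of what its tests demonstrate.

## The constraint network

Every atom is treated as a rigid body with six degrees of freedom. Chemistry
enters purely as *bars* between bodies, each bar removing one relative
degree of freedom:

| interaction | bars | rationale |
|---|---|---|
| locked covalent bond (peptide, carbonyl, carboxylate/amide/guanidinium, rings) | 6 | no internal motion at all |
| rotatable covalent bond | 5 | one dihedral remains |
| hydrogen bond / salt bridge | 5 | like a rotatable bond while it holds |
| hydrophobic tether, ambient | 2 | a soft, slippery contact |
| hydrophobic tether, cold | 1 | the hydrophobic effect weakened by reduced water entropy |

Two conventions deserve comment. First, a *terminal pendant* (a hydroxyl H,
a methyl carbon without modelled hydrogens) is locked to its parent: its
only possible motion would be a spin about its own bond axis, which moves
nothing. Second, parallel bars between the same body pair are summed and
capped at six, since a pair of 6-DOF bodies has only six relative degrees of
freedom.

Hydrogen bonds are detected from donor-H-acceptor triples passing three
gates (donor-acceptor below 3.6 Å, H-acceptor below 2.5 Å, D-H...A angle at
least 110°) and scored with a Mayo-form well

$$E(d,\theta) = V_0\!\left[5\left(\tfrac{d_0}{d}\right)^{12} -
6\left(\tfrac{d_0}{d}\right)^{10}\right]\cos^2\theta,$$

with $V_0 = 8$ kcal/mol and $d_0 = 2.8$ Å, clamped to $[-10, 0]$; at the
well minimum with a linear bond the energy is exactly $-V_0$. The angular
factor $\cos^2\theta$ is a deliberate simplification: published
hybridization-specific angular terms differ in detail, and the rigidity
analysis only consumes the energy ordering of the bonds, which the simple
factor preserves. Charged-group pairs (Asp/Glu carboxylate oxygen against
Lys/Arg/His side-chain nitrogen) within 4.0 Å are classed as salt bridges
and pinned at $-10$ kcal/mol, so they survive every dilution cut-off; when a
residue pair qualifies both ways, the salt-bridge classification wins to
avoid double counting. Hydrophobic tethers join carbon/sulfur atoms of
residues more than two apart in sequence (or on different chains) whose
distance is below the van der Waals sum plus 0.25 Å, keeping only the single
shortest contact per residue pair so one packed patch is not counted
repeatedly.

Waters and crystallization additives are excluded from networks; alternate
conformations default to the highest-occupancy atom (ties by altLoc
identifier) so the network is single-conformer and deterministic; His is
NE2-protonated unless hydrogens say otherwise. Polar hydrogens are placed
internally by ideal geometry (amide H in the peptide plane, 1.0 Å from N,
anti to the preceding carbonyl), which is one of several defensible
conventions; the constraint dump (`writeConstraints`) exists precisely so a
user can audit what the network contains.

## The (6,6) pebble game

Generic rigidity of body-bar frameworks is exactly combinatorial (Tay's
theorem), so no numerics are needed: each body holds six pebbles and a bar
is independent exactly when seven pebbles can be gathered on its endpoints.
The implementation (C++ via Rcpp, as the hot loop of the package) follows
the directed-graph search of the standard pebble-game literature; rigid
clusters are read off by re-gathering pebbles per edge after the game and
taking, for each blocked pair, the set of bodies from which no free pebble
is reachable. Results are provably independent of bar insertion order; the
test suite nevertheless checks this on random multigraphs, and checks the
floppy-mode count and the full cluster partition against an independent
numeric oracle (the rank of a randomly realized rigidity matrix) on
hundreds of seeded instances.

*Rigidity dilution* rebuilds the network at cut-offs of $-1, -2, -3, -4$
kcal/mol (progressively discarding weaker hydrogen bonds) and decomposes
each; the largest-cluster size is non-increasing along the series, and the
cold-regime network — a bar subset of the ambient one — can never be more
rigid. Cluster labels are assigned by size, ties broken by smallest member
id, so outputs are reproducible run to run.

## Elastic network modes

The elastic network uses one node per residue at the Calpha position and
uniform springs (k = 1, arbitrary units — only mode shapes matter
downstream) between all node pairs strictly closer than 10 Å; both chains of
a dimer form one network. The Hessian is the standard anisotropic form,
$-k\,\hat r \hat r^{\mathsf T}$ blocks off-diagonal. Six rigid-body modes
(translations and rotations about the centroid) are constructed
analytically and are exact null vectors.

The ten lowest internal modes, numbered 07-16, are found by *shift-and-invert
block iteration with Rayleigh-Ritz extraction*: the rigid modes are deflated
by a spectral shift, a deterministic starting block of `n + 4` vectors is
repeatedly multiplied by the inverse (one Cholesky factorization, reused),
and Ritz values/vectors are extracted each sweep until every requested mode
satisfies $\|Hv - \lambda v\| \le 10^{-8}\lambda_{\max}$. The block form is
what makes near-degenerate eigenvalue pairs (ubiquitous in symmetric
structures) converge; a single-vector inverse iteration stalls on them.
Degenerate pairs are returned in a stable order with a sign convention
(first visible component positive). The tests compare eigenvalues and
residuals against a full dense diagonalization on every fixture.

A two-node network is a special case worth noting: its rotation about the
bond axis is itself degenerate, so the internal rigid-mode builder drops
null rotation axes, while the exported `trivialModes()` treats collinear
geometry as an error. This is why the textbook dumbbell (one spring, single
internal eigenvalue $2k$) still works end to end.

## Geometric simulation of flexible motion

A mode defined on Calpha nodes is propagated to all atoms by block
replication (each atom inherits its residue's node displacement), normalized
to unit length, and scaled to a 0.1 Å step. After each bias step the
geometry is restored by sequential constraint projection — SHAKE-like
Gauss-Seidel sweeps over three families of pure distance constraints:

* equalities at crystal values: covalent bond lengths, 1-3 distances (angle
  surrogates) and 1-4 distances across locked bonds (dihedral surrogates);
* upper bounds at crystal values for the network's polar and tether
  contacts (they may shorten but not stretch beyond tolerance), retaining
  the non-covalent network selected at $-4$ kcal/mol;
* steric floors at $0.85\times$ the van der Waals sum for non-bonded pairs,
  assembled against the current coordinates each step (pairs within 1-4 of
  each other, and the immediate neighbours of a bonded/constrained contact
  such as the H of a hydrogen bond, are exempt).

A run proceeds for up to 500 steps, saving every 50th frame (frame 0
included, hence at most 11 frames), and halts early the first time a step
cannot be restored to within the 0.1 Å tolerance. Each projection moves
both atoms equally and oppositely, so a run is fully deterministic —
repeated runs are bit-identical — and a pure-translation bias leaves every
internal distance unchanged to floating-point accuracy, which the tests
assert at $10^{-9}$. This scheme deliberately replaces ghost-template
approaches with plain distance projection: the acceptance surface (restore
within 0.1 Å or halt) is identical and the implementation has no tunable
internals beyond the sweep budget (200 per step).

## Synthetic fixtures: what they do and do not show

All tests run without downloads on generated inputs:

* `idealHelix(n)` builds peptides from internal coordinates (φ = −57°,
  ψ = −47°, standard bond geometry, fixed common rotamers) so the i→i+4
  hydrogen-bond ladder falls inside the detection gates by construction.
  Side-chain rotamers were chosen once so that an isolated helix is free of
  steric-floor violations; the builder supports the residues needed by the
  fixtures (Gly, Ala, Ser, Cys, Thr, Leu, Lys, Glu, Asp, Arg, Phe).
* `twoHelixDimer()` packs two 18-residue helices antiparallel with designed
  threonine contact faces and a Lys–Asp salt bridge. The Thr methyls give
  inter-chain tethers, the hydroxyls inter-chain hydrogen bonds, and under
  the default packing the ambient network at $-1$ kcal/mol welds both helix
  cores into one rigid cluster spanning the chains, while the cold network
  leaves two separate helices — a miniature of the ambient/cold contrast
  the method is designed to expose. The interface is deliberately snug;
  a crude uniform steric floor flags a few contacts there, which is why
  the geometric-simulation contract tests run on the (clash-free) helix.
* `randomBodyBar()` draws seeded multigraphs (≤ 8 bodies in the tests) as
  the substrate for the rank oracle, and `noisyEnsemble()` adds seeded
  isotropic Gaussian noise for the RMSF calibration against the closed form
  $\sigma\sqrt{3}\sqrt{(n-1)/n}$.

Problem sizes in the routine test run — a 20-residue helix, a 36-residue
dimer, graphs of at most 8 bodies, 100-instance oracle sweeps, 500-step
simulations — were chosen as the smallest systems that exercise every code
path nontrivially; all scale linearly or better to protein-sized inputs.
What passing tests demonstrate is the correctness of the algorithms: exact
agreement with the rigidity oracle, spectral accuracy against dense
diagonalization, and the constraint contract of the simulator. What they
cannot demonstrate is agreement with published counts on deposited crystal
structures, which depend on unstated geometric criteria of the original
detection tools (tether slop, eligible elements, salt-bridge cutoffs);
the interaction parameters are therefore exposed as an
`interactionParams()` object and the constraint dump makes any discrepancy
on real inputs localizable.

## Statistics conventions

RMSD uses Kabsch superposition (proper rotation; cross-checked against an
independent implementation in the tests). RMSF superposes frames onto the
ensemble mean with one mean re-iteration; superposition can be disabled,
and the noise-calibration test does so because the closed form describes
unaligned noise. The B-factor fold change for a region divides the region's
mean Calpha B-factor by the mean over *all* Calpha atoms of the model (both
chains); the region is a parameter, with the cap/lid convention of
HSL-family esterases (residues 7-42) as the default in the report pipeline.
SASA is Shrake-Rupley with a deterministic Fibonacci point lattice (960
points/atom, 1.4 Å probe, hydrogens excluded by default); interface area is
the standard half-sum $\tfrac12[S(A)+S(B)-S(AB)]$. The composition census
prefers SEQRES so counts do not depend on disordered residues missing from
coordinates.

## Known limitations

* No aromatic stacking, cation-π, metal-coordination or explicit-solvent
  terms in the network.
* Hydrogen placement is internal and ideal-geometry based; structures
  prepared with external protonation tools will differ in borderline
  hydrogen bonds.
* The geometric simulation has no energetics: it maps the *reach* of a
  motion, not its free-energy cost, and hydrogen bonds never break or
  reform during a run.
* The all-atom mode projection is per-residue block replication; side-chain
  directions are therefore inherited, not modelled.
* mmCIF input is read-only; all outputs are PDB-format.
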