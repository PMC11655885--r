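---
title: "Comparative conformational dynamics: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative conformational dynamics: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajscape)
```

trajscape compares how different ligands reshape a receptor's
conformational landscape in molecular-dynamics (MD) ensembles. The typical
use case is a set of GPCR-inverse-agonist complexes simulated under
identical protocols, where the scientifically interesting differences are
subtle: a slightly wider intracellular crevice, a loosened salt bridge, a
shifted population of intracellular substates. The package computes four
complementary per-ensemble readouts plus the static structure-comparison
measurements used alongside them, and ships a synthetic-ensemble generator
with planted ground truth so that every estimator can be validated without
any external data.

## The ensemble model

All dynamics metrics consume an `Ensemble`: an ordered set of frames over
one topology. Frames before the burn-in fraction (default 0.5 when reading
trajectories: analysis runs on the equilibrated last half) are excluded
everywhere; this choice is recorded in every output. Multi-model PDB is
the mandatory, self-contained frame format; all coordinates are in
Angstrom, residue numbering is the author numbering of the input, and
every distance criterion in the package uses heavy atoms only, since
experimental depositions generally lack hydrogens.

## Surface topography

For atom $k$, with $\Omega_k(t)$ the set of heavy atoms within $d$ of $k$
at time $t$ and $M$ the heavy-atom count,

$$F_k = \left\langle N_{\Omega_k(t)}^{-1} \sum_{i \in \Omega_k(t)}
\sum_{j \neq i}^{M} A_i\, e^{-B_i r_{ij}(t)} \right\rangle_t .$$

The inner sum is an exponential contact density of the kind used for fast
analytic estimates of solvent-accessible surface area: atoms at the bottom
of deep, narrow pockets accumulate many short contacts and score high,
atoms on protuberances score low, so residue-averaged $F$ maps concavity
onto the molecular surface. Parameters and defaults:

* `neighborhood_radius` ($d$): 6.0 A. Not a measured constant; chosen
  commensurate with first-shell heavy-atom contact distances and echoed in
  the output metadata as a configuration default.
* `A`, `B`: per-element contact-model parameters. No published table is
  assumed; the default is uniform $A = 1$, $B = 0.5\,\mathrm{A^{-1}}$,
  which preserves the concavity *ordering* the score is used for
  comparatively. A per-element table can be supplied when calibrated
  contact-model parameters are available.
* The central atom belongs to its own neighborhood by default
  (`include_self`), which makes the two-atom closed form symmetric:
  two isolated atoms at distance $r$ both score exactly $A e^{-Br}$.

$F$ depends only on pairwise distances, hence is exactly invariant under
rigid motion, and the time average is linear: pooling ensembles averages
$F$ with frame-count weights. Both properties are asserted in the tests,
along with equality (to $10^{-12}$) with a naive double-loop oracle.

## Local flexibility

For residue $K$, the environment $\Omega_{K,0}$ collects the sidechain (or
backbone) heavy atoms of every residue having at least one heavy atom
within $d$ (default 6.0 A) of $K$ in the reference frame ($t = 0$ by
default). For each frame, the C-alpha atoms of all residues contributing
to $\Omega_{K,0}$ define an optimal rigid superposition onto the
reference; with $r_i(t)$ the post-fit displacement of atom $i$ from its
reference position,

$$G_K(t) = \Big( N^{-1} \sum_{i \in \Omega_{K,0}} r_i^2(t) \Big)^{1/2},
\qquad H_K = \big\langle (G_K(t) - \bar G_K)^2 \big\rangle_t^{1/2} .$$

$H_K$ is the width of the distribution of the environment's RMS
displacement — the local region is treated as a liquid with random atomic
fluctuations, and $H$ is the width of that (assumed normal) distribution,
computed nonparametrically with the population (1/N) convention
(configurable). The superposition step removes rigid-body motion exactly:
a zero-noise ensemble with per-frame global rotations and translations has
$H = 0$ to machine precision. Residues whose environment contains fewer
than three C-alpha-bearing residues make the fit ill-posed; they raise an
error when queried singly and are recorded as `NA` (with a warning) in
maps. Flexible loops or tether artifacts are excluded simply by excluding
them from the selection.

Two properties of $H$ matter when interpreting validation results:

* $H$ grades the *environment*, not the residue in isolation. A planted
  per-residue amplitude profile is therefore recovered in rank order only
  where neighboring amplitudes are similar (a smooth profile) or the
  contrasted block is spatially isolated by more than one environment
  radius. The recovery tests use a graded, tie-free profile along a single
  helix; a two-level profile with tied ranks caps the achievable Spearman
  correlation at 0.87 for purely arithmetic reasons (rank ties), so group
  separation is asserted for that fixture instead.
* Scaling: doubling all amplitudes doubles $H$ exactly for a fixed
  environment. Since membership is resolved in the (noisy) reference
  frame, the scaling test pins the reference frame to the noiseless base
  geometry.

## Interaction networks

Contacts are detected per frame from distance-only criteria, deliberately
without any angular term: a polar (H-bond/salt-bridge class) contact
exists when the minimum distance between sidechain donor/acceptor atoms of
two residues is strictly below $\delta_{AD} = 3.0$ A, and a nonpolar
(hydrophobic/dispersion) contact when the minimum sidechain carbon-carbon
distance is strictly below $\delta_{CC} = 4.8$ A. The strict inequality at
the cutoff is part of the definition and is tested at the boundary.
Donors/acceptors of standard residues come from a fixed template table
(Ser OG, Thr OG1, Tyr OH, Asn OD1/ND2, Gln OE1/NE2, Asp OD1/OD2, Glu
OE1/OE2, Lys NZ, Arg NE/NH1/NH2, His ND1/NE2, Trp NE1; Cys SG excluded by
default); heteroatom groups (ligands, waters) are typed by element, with
halogens (F, Cl, Br, I) counting as polar partners by default so that
potential halogen bonding is folded into the polar class without modeling
its geometry. A backbone-inclusive scope is available for networks that
involve backbone carbonyls/amides.

An edge's *persistence* is the fraction of analyzed frames in which the
contact holds — a proxy for interaction strength. Persistence is
normalized over post-burn-in frames (recorded in the output), is invariant
to frame order, and concatenates linearly across pooled ensembles. The
reported `mean_min_distance` averages the per-frame minimum distance over
the frames where the edge is present (the geometry of the interaction when
formed). Salt bridges get a convenience report restricted to Asp/Glu
carboxylate oxygens versus Arg/Lys/His sidechain nitrogens; pairs that
never form are still listed with persistence 0.

## Conformational substates

The clustering metric is the pairwise minimum RMSD (optimal rigid
superposition) over a C-alpha selection — typically the intracellular
portion of the receptor with flexible loops excluded. The region is always
an explicit selection; the package never guesses it. Substates are
extracted by a spherically constrained density-based procedure in the
DBSCAN family, concretized as greedy densest-ball extraction:

1. for every unassigned frame, count the unassigned frames within
   $R$ (default 1.2 A, strict `<`);
2. the frame with the largest count becomes the next medoid centroid
   (ties go to the lowest frame index);
3. its ball is removed as one substate;
4. stop when the best remaining ball's density — members relative to
   *all* sampled frames — no longer exceeds the gate $p_i > 5\%$.

Unclaimed frames are thermal noise. This concretization was chosen because
it satisfies every stated constraint of the method family — density-based
selection, spherical clusters of radius $R$, the 5% population gate,
remainder classified as noise — while being fully deterministic: identical
inputs give identical partitions, and permuting the frames permutes
memberships consistently. Densities come out non-increasing by
construction. Centroids are medoids (actual frames), since only a distance
matrix exists.

## Structure comparison

Superpositions use the Kabsch algorithm (3x3 SVD with a proper-rotation
sign correction); degenerate (collinear or coincident) point sets are
rejected. Atom pairing across structures is by identical
`(chain, residue number, atom name)`, with unmatched atoms dropped and
counted. The domain rotation angle between two structures first removes
the global pose difference by superposing on an alignment pairing
(typically all receptor C-alphas), then extracts the angle of the optimal
rotation between the domain point sets from its trace, clamped into
$[-1, 1]$ before the arccos for numerical safety near 0 and 180 degrees.
Planted rotations across 5-175 degrees are recovered to better than
$10^{-6}$ degrees. Ligand contact shells report every receptor residue
with a heavy atom within the cutoff (4.0 A default, inclusive) of a ligand
heavy atom, with per-residue minimum distances and realizing atom pairs;
minimum distances between selections break ties deterministically toward
the lowest atom-index pair.

## The synthetic-ensemble generator

The generator emulates exactly the statistical structure the metrics are
designed to detect, with every draw controlled by one explicit integer
seed:

* **Geometry**: idealized antiparallel helix bundles (rise 1.5 A, 100
  degrees per residue, C-alpha radius 2.3 A, adjacent helix axes 10 A
  apart — the packing scale of a transmembrane bundle), backbone N/CA/C/O
  plus one sidechain pseudo-atom typed by residue (ASP gets a carboxylate
  oxygen, ARG a guanidinium nitrogen, and so on), so contact typing works
  unchanged. A 0.05-A seeded perturbation breaks exact symmetry.
* **Substates**: a mixture of centroids displaced along mutually
  orthogonal per-residue fields with net translation projected out, scaled
  so every centroid pair sits at the requested raw C-alpha RMSD
  (superposed RMSD is marginally smaller, which is immaterial at the
  planted 5 A versus 0.2 A jitter used in validation); frames draw their
  state from the planted weights and add isotropic Gaussian jitter.
  Separability requires the displacement to exceed twice the jitter.
* **Fluctuations**: per-residue Gaussian amplitudes on sidechain,
  backbone, or all atoms, with an optional per-frame rigid-body jitter (up
  to 8 degrees / 2 A) to exercise the superposition step.
* **Contacts**: donor-acceptor occupancies realized by *exact frame
  counts* in a seeded random frame order (contact distance < 3 A <
  apart distance), so persistence assertions are exact rather than
  binomial.
* Generated ensembles set `burn_in_fraction = 0`: they represent only the
  production portion a study would analyze, and exact-count contracts
  (occupancy 0.40 over 100 frames gives persistence exactly 0.40) hold
  over all frames.

What the generator does *not* emulate: force-field correlations,
anisotropic and collective motions, solvent and membrane structure,
rotamer jumps, or kinetics. Passing the validation suite therefore
demonstrates estimator correctness — that each statistic recovers the
quantity it defines, at the planted effect sizes, under Gaussian noise —
not that those statistics are sufficient summaries of real MD ensembles.

## Validation conditions and problem sizes

The test suite and the acceptance script (`scripts/acceptance.R`) rerun
the full recovery battery at fixed, documented scales chosen to exercise
the estimators well inside their operating regime: two-substate mixtures
with weights 0.6/0.4 over 500 frames (densities recovered within 0.03,
membership agreement at least 99%); an exact 58/38/4% three-ball
construction, whose 4% ball must fall below the 5% gate into noise; a
graded 0.2-1.0 A fluctuation profile over 24 residues and 500 frames
(Spearman at least 0.9); planted occupancy 0.40 over 100 frames
(persistence exactly 0.40); rotation sweeps over 5-175 degrees (recovery
to 1e-6 degrees); and brute-force oracle equivalence on clouds of up to
~80 atoms and 10 frames. Comparisons against deposited experimental
structures (receptor C-alpha RMSDs, a fusion-domain rotation, ligand
contact distances) are included as a separate acceptance block that
fetches the models from the RCSB PDB at run time and therefore requires
network access.

## Known limitations

* Distance-only contact criteria admit geometrically poor H-bonds by
  design; this is a fidelity choice, not an oversight, and is pinned by a
  test.
* The topography A/B defaults are uniform; absolute values of $F$ are not
  comparable across parameter tables, only orderings within one table.
* Persistence conflates occupancy with multiplicity: an edge counts once
  per frame regardless of how many atom pairs qualify.
* The substate procedure is greedy; like all medoid-ball methods it can
  split elongated basins that a kinetic analysis would merge. Substates
  carry no kinetic meaning here.
* mmCIF input and binary trajectory formats (DCD/XTC) are not parsed;
  multi-model PDB is the supported interchange format.
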