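# trajscape

Comparative conformational-dynamics analysis of molecular-dynamics (MD)
ensembles, written for the situation where several ligand-receptor
complexes — say, a GPCR bound to different inverse agonists — have been
simulated under identical protocols and the question is *where and how the
ligands reshape the receptor's conformational landscape*. The differences
that matter (a widened intracellular crevice, a loosened salt bridge, a
shifted substate population) are too subtle for global RMSD/RMSF
summaries, so trajscape computes local, comparable readouts:

- **Surface topography** `F_k` — the time-averaged exponential contact
  density of each atom's neighborhood,
  `F_k = ⟨ N_Ω⁻¹ Σ_{i∈Ω_k(t)} Σ_{j≠i} A_i exp(−B_i r_ij(t)) ⟩_t`,
  which grades local concavity (pocket bottoms score high, protuberances
  low) and, residue-averaged, exports as a surface heatmap.
- **Local flexibility** `H_K` — the width of the distribution of the RMS
  displacement `G_K(t)` of residue K's reference-frame environment, after
  optimally superposing each frame's environment C-alphas onto the
  reference: `H_K = ⟨(G_K − Ḡ_K)²⟩_t^{1/2}`. Rigid-body motion cancels
  exactly; what remains is local, liquid-like disorder.
- **Interaction networks** — per-frame polar contacts (sidechain
  donor/acceptor distance < 3.0 Å) and nonpolar contacts (sidechain
  carbon-carbon distance < 4.8 Å), distance-only by design, aggregated
  into edges weighted by *persistence* (fraction of analyzed frames), a
  proxy for interaction strength; includes a salt-bridge report.
- **Conformational substates** — a spherically constrained, deterministic
  density-based clustering (DBSCAN family) on the pairwise superposed
  C-alpha RMSD matrix of a chosen region: balls of radius R = 1.2 Å are
  extracted greedily by density, substates must hold > 5% of the frames,
  and the remainder is thermal noise.
- **Structure comparison** — Kabsch superposition RMSD, inter-structure
  domain rotation angles (e.g. a fusion-domain swing-out), ligand contact
  shells within a cutoff, and minimum-distance queries.
- **Synthetic ensembles with planted truth** — helix-bundle toys with
  planted substate mixtures, per-residue fluctuation amplitudes, exact
  contact occupancies and rigid domain rotations, so every estimator is
  validated end to end without external data.

Structures are read/written as PDB, ensembles as multi-model PDB; all
distance criteria use heavy atoms; residue numbering and chain IDs are
preserved verbatim.

## Worked example

Plant a 60/40 two-substate mixture (centroids 5 Å apart in C-alpha RMSD,
0.2 Å thermal jitter) and recover it:

```r
library(trajscape)

bundle <- make_bundle(n_helices = 3, residues_per_helix = 8, seed = 1)
truth  <- substate_truth(n_states = 2, weights = c(0.6, 0.4),
                         centroid_displacement = 5, within_sigma = 0.2)
sim  <- make_substate_ensemble(bundle, truth, n_frames = 500, seed = 2)
part <- find_substates(sim$ensemble, select_atoms(bundle, "calpha"))
part
#> SubstatePartition: 2 substate(s), 0 noise frame(s) of 500
#>   substate 1: centroid frame 2, density 0.590
#>   substate 2: centroid frame 1, density 0.410
```

The recovered densities 0.590/0.410 match the realized label frequencies
(295/205) exactly — every frame joins the ball around the correct planted
centroid and none is lost to noise. Flexibility works the same way: plant
a graded 0.2-1.0 Å side-chain amplitude profile along a helix and the
per-residue width `H` reproduces its ranking,

```r
helix <- make_bundle(1, 24, seed = 1)
sigma <- seq(0.2, 1.0, length.out = 24)
ens   <- make_fluctuation_ensemble(helix, sigma, n_frames = 500, seed = 3)
fmap  <- fluctuation_map(ens, select_atoms(helix, "protein"))
head(as.data.frame(fmap), 4)
#>   chain resid resname     value
#> 1     A     1     ALA 0.1083818
#> 2     A     2     ALA 0.1169008
#> 3     A     3     ALA 0.1149217
#> 4     A     4     ALA 0.1174429
cor(sigma, fmap$value, method = "spearman")
#> [1] 0.999
```

(`H` is smaller than the planted per-atom sigma because it is the width of
the environment's RMS displacement, which concentrates as the environment
grows — values are compared within a map, not against sigma directly.)

`run_report()` chains topography → flexibility → interactions → substates
over one analyzed frame set from a single `analysis_config()` (or
YAML/JSON file), writes CSV/TSV/JSON plus B-factor-encoded PDB heatmaps,
and `compare_reports()` aligns two runs residue-by-residue into the
ligand-versus-ligand difference tables that are the core comparative
readout.

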