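# rampclamp

Trajectory analysis and a desk-scale pulling engine for "ramp-clamp"
steered-dynamics studies of receptor–ligand complexes, modelled on the
CD47/CD172a system: an immune-checkpoint interaction in which tensile force
and an N-terminal pyroglutamate modification of CD47 modulate binding to
CD172a on myeloid cells.

Analyses of such simulations revolve around a small set of trajectory
metrics, and this package implements all of them as tested, reusable
functions:

* **Structure/trajectory IO** — fixed-width PDB (ATOM/HETATM/MODEL subset,
  pyroglutamate handled as a normal residue), multi-frame XYZ, force-trace
  CSV, and a deterministic atom-selection language.
* **Geometry** — Kabsch superposition, Cα-RMSD and per-residue RMSF, radius
  of gyration, and the three binding-pocket descriptors: the loop-centroid
  distance *H*, the strand-vs-reference-line angle *α*, and the
  inter-strand angle *θ* (strand axes via oriented principal components).
* **Surface area** — Shrake–Rupley SASA with a 1.4 Å probe on a
  deterministic golden-spiral lattice, and buried interface area
  ΔSASA = SASA(A) + SASA(B) − SASA(AB).
* **Hydrogen bonds** — geometric detection (donor–acceptor ≤ 3.5 Å, D–H–A
  linearity deviation ≤ 30°), per-frame interfacial bond counts N_HB,
  residue-pair occupancy (survival-ratio) tables with replicate mean ± SD,
  two dissociation-probability estimators, and force-response typing of
  bonds into force-insensitive (I), force-enhanced (II) and force-weakened
  (III) classes.
* **Energetics** — single-trajectory MM-GB/SA-style decomposition:
  Coulomb + Lennard-Jones gas term, generalized-Born polar solvation
  (Still f_GB, HCT effective radii), γ·SASA + β nonpolar term, with an
  exact additivity identity E_B = ΔE_gas + ΔG_polar + ΔG_nonpolar.
* **Pulling engine** — coarse-grained elastic-network model with overdamped
  Langevin dynamics (compiled core), implementing constant-velocity
  (force-ramp) pulling with a 34.74 pN/nm virtual spring at 5 Å/ns, a
  switch to force-clamp at the 25 pN setpoint, one-anchor (mode 1) and
  two-anchor midpoint (mode 2) loading geometries, breakable interface
  springs so rupture exists, and rupture-force extraction from smoothed
  force–time traces.
* **Synthetic data** — seeded generators for two-chain complexes with
  explicit D–H···A interfaces at prescribed per-bond occupancies (iid or
  Markov-correlated in time), ideal β-strand Cα traces, and
  ramp/peak/plateau force traces — every fixture carries its ground truth.
* **Pipeline** — `analyze_trajectory()` and `smd_experiment()` orchestrate
  replicate runs, mean ± SD aggregation, Welch comparisons with star codes,
  tidy CSV reports and reproducibility manifests.

## Worked example

Generate three replicate trajectories of a 12-bond synthetic interface at
the catalogue occupancies for the pyroglutamate-modified terminus, then run
the full static analysis:

```r
library(rampclamp)
pr <- reference_interface_pairs()
spec <- interface_spec(occupancies = pr$occ_wt)
trajs <- lapply(1:3, function(r)
  jitter_trajectory(build_complex(spec), spec, n_frames = 1000, seed = 100 + r))
rep <- analyze_trajectory(trajs, chains_a = "A", chains_b = "B", condition = "wt")
rep
#> analysis_report: 3 replicates, condition 'wt'
#>             metric condition n         mean           sd flag
#> 1         nhb_mean        wt 3 5.5233333333 7.664420e-02
#> 2 f_d_independence        wt 3 0.0001105755 1.380053e-05
#> 3    f_d_empirical        wt 3 0.0023333333 1.154701e-03
head(rep$occupancy, 4)
#>                pair  mean         sd n_runs condition
#> 1 B:LYS53->A:GLU106 0.549 0.01752142      3        wt
#> 2  B:LYS53->A:GLU97 0.329 0.02553429      3        wt
#> 3 B:LYS96->A:GLU104 0.665 0.02426932      3        wt
#> 4  B:LYS96->A:GLU97 0.664 0.00781025      3        wt
```

The mean interfacial bond count (5.52 ± 0.08) matches the sum of the
generator's occupancy targets (5.53), and each residue-pair occupancy
(e.g. LYS53→GLU106 at 0.549) recovers its target (0.54) within replicate
noise. The two dissociation estimators differ because the empirical
all-bonds-broken frequency is resolution-limited at 1000 frames, while the
independence product extrapolates from per-bond occupancies.

A pulling experiment comparing the one-anchor and two-anchor loading
geometries on a two-strand interface:

```r
s <- md_structure(rbind(build_strand(10, chain_id = "A")$atoms,
                        build_strand(10, chain_id = "B", origin = c(5, 0, 0))$atoms))
m <- build_enm(s, selection = "all", cutoff = 7, k_intra = 2, k_interface = 0.8)
sys <- list(one_anchor = set_loading(m, 1, fixed = 1L, steered = 11L),
            two_anchor = set_loading(m, 2, fixed = c(1L, 10L), steered = 11L))
ex <- smd_experiment(sys, smd_protocol(ramp_ns = 8, seed = 7), n_rep = 3, clamp = FALSE)
ex$summaries
#>             metric  condition n     mean       sd flag
#> 1 rupture_force_pN one_anchor 3 135.7152 3.010087
#> 2 rupture_force_pN two_anchor 3 137.5091 1.079088
```

Anchoring both ends of the held chain (the geometry that models a
membrane-proximal disulfide constraint) yields a higher mean rupture force —
the qualitative two-anchor strengthening effect, at engine scale.

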