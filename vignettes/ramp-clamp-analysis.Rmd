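---
title: "Ramp-clamp steered-dynamics analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ramp-clamp steered-dynamics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rampclamp)
```

## Scope and units

`rampclamp` re-implements, at desk scale, the complete trajectory-analysis
battery used in ramp-clamp steered-dynamics studies of receptor–ligand
complexes such as CD47/CD172a: deviation and fluctuation metrics (Cα-RMSD,
RMSF), compactness (Rgyr), solvent-accessible and buried interface area,
geometric hydrogen-bond statistics (number, occupancy, dissociation
probability, force-response typing), a decomposed binding-energy estimate,
the three pocket-geometry descriptors *H*, *α* and *θ*, and rupture-force
extraction — together with a coarse-grained pulling engine that realises the
ramp→clamp loading protocol so the whole pipeline can be exercised end to
end on synthetic inputs with known ground truth.

One convention holds everywhere: coordinates in Å, times in ns, forces in
pN, energies in kcal/mol. `rc_constants()` owns the three bridging constants
(Coulomb constant 332.0636 kcal·Å·mol⁻¹·e⁻², k~B~ = 0.0019872
kcal·mol⁻¹·K⁻¹, and 1 pN·Å = 0.0143836 kcal/mol); no other file contains a
unit factor. Mixing Å/nm/pN/ns silently is the classic failure mode of this
kind of analysis, and a single owner prevents it.

## Structures, trajectories and selections

Structures are plain atom tables (`md_structure`); trajectories share one
topology with an `n_frames × n_atoms × 3` array and strictly increasing
times. The PDB reader covers the ATOM/HETATM/MODEL/ENDMDL/TER subset:
multi-MODEL files become trajectories, pyroglutamate (PCA) is parsed as an
ordinary residue, elements are inferred from the atom-name columns when the
element field is blank, and the default altloc policy keeps the `'A'`/blank
conformer (the common crystallographic convention). Residue numbers are
taken from the file as-is; no renumbering. Selections use a small
deterministic expression language (`"name CA and chain A"`,
`"resseq 50-60 and chain B"`) that always resolves in file order, so every
derived quantity is reproducible from the expression alone.

Crystal structures usually lack hydrogens. Rather than inventing them, the
H-bond layer exposes a documented distance-only fallback (below); synthetic
fixtures always carry explicit hydrogens so the full angular criterion is
exercised by tests.

## Geometry metrics

Superposition is Kabsch (SVD, proper rotation enforced), unweighted over Cα
atoms by default since the quantity of interest is the plain Cα-RMSD;
optional weights support mass-weighted fits. RMSF superposes frames onto an
iteratively refined mean structure (two passes) before measuring per-residue
fluctuations; whether the fit uses the whole complex or one chain is the
caller's choice via `fit_selection`, since published fluctuation profiles
are sensitive to that choice and the convention is rarely stated.

The three pocket descriptors follow their geometric definitions: *H* is the
distance between Cα centroids of two loops (e.g. the CD and DE loops of the
receptor's membrane-distal domain, with the CD loop spanning residues
50–60 in the default numbering); *α* is the angle between a strand axis and
the line through two reference Cα atoms; *θ* is the angle between two strand
axes across the interface. A strand axis is the first principal component of
the ordered Cα coordinates, sign-fixed so it points N→C. "The angle between
two strands" is ambiguous in the literature — oriented axes give values in
[0°, 180°] that can straddle 90°, unoriented ones fold into [0°, 90°]. Both
are exposed; oriented is the default because reported values near and beyond
90° imply an orientation convention. All arccos arguments are clamped to
[−1, 1] to absorb rounding.

## Surface areas

SASA uses Shrake–Rupley with a 1.4 Å water probe and a golden-spiral
(Fibonacci) point lattice — deterministic, so repeated runs agree bitwise;
960 points per atom gives ~0.5% accuracy on isolated spheres and <1%
against a dense-sampling oracle on clusters. Because the lattice is fixed in
the laboratory frame, totals are rotation-invariant only up to the sampling
error (≪1%), which the tests state explicitly. Buried interface area is
the full ΔSASA = SASA(A) + SASA(B) − SASA(AB), not halved; magnitudes of
~9–10 nm² for an Ig-domain interface are consistent with the full-ΔSASA
convention, and a `halved` flag serves the per-side convention.

## Hydrogen bonds

A donor–hydrogen–acceptor triplet is a bond when the donor–acceptor distance
is ≤3.5 Å and the deviation of the D–H–A angle from linearity is ≤30° — the
VMD convention, where the cutoff applies to 180° minus the angle at the
hydrogen, not to the raw angle. Donors are N/O atoms with an attached
hydrogen (≤1.2 Å in the topology frame), acceptors are N/O atoms.
Occupancy (survival ratio) is the fraction of frames a bond is present,
aggregated to residue pairs by per-frame union of the atom-level triplets,
because published occupancy tables list residue pairs, not atom triplets.
Replicates are aggregated as mean ± sample SD (n−1), the three-run
convention.

Two dissociation-probability estimators are provided and deliberately
labelled non-equivalent to kinetic-model rates: the independence product
Π(1−occ~i~), exact for independently fluctuating bonds, and the empirical
fraction of frames with zero interfacial bonds (with the rule-of-three
bound 3/n when no such frame is observed). They order conditions by
interface persistence; absolute magnitudes depend strongly on bond
correlations, which is why both are reported.

Force-response typing compares mean occupancy under load against the static
state: type II (force-enhanced) at Δ ≥ δ~min~, type III (force-weakened) at
Δ ≤ −δ~min~, type I otherwise, with δ~min~ = 0.05 as the default — a
threshold chosen once as the smallest change distinguishable from three-run
noise at typical occupancy SDs (±0.01–0.13); no published value exists. An
optional Welch gate demotes non-significant calls to type I. Typing is
antisymmetric under swapping the conditions, which the tests enforce.

## Binding energy

The decomposition is the standard single-trajectory MM-GB/SA shape:
gas-phase Coulomb + Lennard-Jones (no cutoff — systems here are small),
polar solvation by generalized Born (Still's f~GB~ with
Hawkins–Cramer–Truhlar pairwise-descreening effective radii, ε~in~ = 1,
ε~out~ = 78.5), nonpolar solvation as γ·SASA + β (γ = 0.00542
kcal·mol⁻¹·Å⁻², β = 0.92 kcal/mol). GB rather than a Poisson–Boltzmann
solver is a deliberate choice: it is testable against closed forms (the
single-ion Born energy, the two-charge formula, the infinite-separation
limit) and adequate for ranking desk-scale fixtures. Each Δ term is
complex-minus-parts on the same geometry; the additivity identity
E~B~ = ΔE~gas~ + ΔG~polar~ + ΔG~nonpolar~ is exact by construction. In the
three-state difference the constant β does not cancel (it would leave a
spurious −β for two non-interacting chains), so `binding_energy()` uses
β = 0 while `nonpolar_surface()` keeps 0.92 for absolute energies. No
entropy term is included. Parameters (charges, LJ, intrinsic Born radii)
come from a plain-text table keyed by residue and atom name; fixtures ship
complete parameter sets.

## The pulling engine

The engine is an elastic-network model — one bead per Cα, harmonic springs
at native distances within a 10 Å cutoff — integrated with overdamped
(Brownian) dynamics: dx = F/γ·dt + √(2k~B~T·dt/γ)·ξ. The per-step core is
compiled (Rcpp) because the statistical checks below need 10⁶–10⁷ steps.
Defaults: k~intra~ = 1 kcal·mol⁻¹·Å⁻², friction γ = 0.05
kcal·mol⁻¹·ns·Å⁻² (bead diffusion k~B~T/γ ≈ 12 Å²/ns, a realistic
residue-scale mobility; relaxation time γ/k = 0.05 ns), dt = 10 fs, giving
a stability ratio k·dt/γ ≈ 2·10⁻⁴ — the engine refuses to run past
k·dt/γ > 0.1 and suggests a step size. Temperature defaults to 300 K; the
seed is mandatory and runs are bitwise reproducible.

Loading follows the two published geometries. Mode 1 fixes one anchor bead
and pulls the steered bead along the anchor→steered line; mode 2 fixes two
anchors (modelling an additional membrane-proximal disulfide constraint)
and pulls along the line from their midpoint to the steered bead. The
direction is computed from the t = 0 geometry and held constant (the
standard moving-spring convention). The virtual spring (34.74 pN/nm)
connects the steered bead to a dummy atom moving at 5 Å/ns; force is the
signed projection of the spring extension on the pulling direction. When
that force first reaches 25 pN the run switches to force-clamp, holding the
setpoint constant on the steered bead. A ramp that never reaches the
setpoint is reported protocol-incomplete rather than raised as an error,
mirroring how incomplete runs are flagged, not discarded.

Rupture requires a breakable interface: inter-chain springs get a weaker
stiffness (0.2× by default) and are removed permanently once stretched past
2× their rest length. This breakage rule is engine-specific plumbing — it
exists so that a rupture force exists at desk scale — and is not a claim
about the physical system. Rupture force is the global maximum of the
running-mean-smoothed ramp-phase force.

Physics checks anchor the engine to closed forms: a rigid-anchor ramp must
produce exactly k·v = 17.37 pN/ns of force growth; a clamped
zero-rest-length tether must sit at extension F/k (Hooke) within three
standard errors; a free thermal bead must satisfy equipartition
(var = k~B~T/k within 5%); and a zero-temperature run must track a
reference ODE integration within 10⁻⁶ Å.

## Synthetic data: what it emulates and what it does not

The generators produce every input class with known ground truth. The
interface generator realises a catalogue of twelve donor/acceptor residue
pairs (the catalogue's static occupancies for the PCA1- and GLN1-terminus
forms are the generator's default targets) as explicit D–H···A sites at
2.9 Å / 5° — comfortably inside the cutoffs — plus decoy sites permanently
outside them. Per frame, each bond is toggled by moving its acceptor
radially by +1.5 Å (to 4.4 Å), an unambiguous absent state chosen to keep
tests away from borderline-cutoff flakiness. Temporal models: iid Bernoulli
draws, or a sticky Markov chain (keep the previous state with probability
p\_stay, else redraw), whose stationary occupancy equals the target exactly
and whose lag-k autocorrelation is p\_stay^k — enough structure to test
effective-sample-size-aware occupancy inference. Strand and force-trace
generators carry their axes and peak values as ground-truth attributes.

What passing tests therefore show: the estimators recover known occupancies
with calibrated uncertainty; the detectors match exhaustive enumeration; the
engine obeys its own statistical mechanics. What they do not show: anything
about all-atom force fields, explicit solvent, or real binding-pocket
geometry. Synthetic complexes have no rotamers, no physical packing, and
bond toggling is geometric, not energetic. Published ensemble means from
solvated 40–50 ns simulations (binding energies of hundreds of kcal/mol,
rupture forces of hundreds of pN) are outputs of that larger machinery and
are used here only to set fixture scales, never as expected values.

## Problem sizes and statistics

The shipped analyses use deliberately modest sizes chosen for tight
statistical checks: 2000-frame trajectories for occupancy recovery (3-SE
intervals cover the targets in ≥95% of 100 repetitions), three replicates
for mean ± SD aggregation (the standard convention), 100 ns single-bead runs
for equipartition (pooled over coordinates, SE ≈ 1.2%), and 6–8 ns ramps
for rupture ensembles. The comparison layer defaults to Welch's
unequal-variance t-test — safer than the pooled test at n = 3 — with the
classical pooled variant behind a flag; star codes follow the usual
0.05/0.01/0.001 caption convention. Heavier omnibus designs (two-way ANOVA
with post-hoc corrections) are out of scope for the synthetic experiments
this package runs.

## Known limitations

* Distance-only H-bond detection (no hydrogens) overcounts relative to the
  angular criterion; it is flagged in every report that uses it.
* GB with HCT radii is a screening model: absolute polar energies for dense
  many-atom systems carry the usual GB biases, which is why tests pin it to
  closed forms and limits rather than literature energies.
* The ENM breakage rule makes rupture forces engine-scale quantities;
  only their orderings (stiffer interface ⇒ stronger; two anchors ⇒
  stronger under the same load path) are meaningful.
* The dissociation-probability estimators are not kinetic off-rates; they
  are occupancy-based summaries with stated independence assumptions.
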