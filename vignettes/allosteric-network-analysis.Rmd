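---
title: "Network-centric analysis of protein conformational ensembles"
author: "allonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-centric analysis of protein conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonet)
```

## What this package computes

Allosteric regulation in multidomain proteins -- the Hsp70/Hsp110
chaperones are the motivating system -- is increasingly analysed through the
lens of residue interaction networks built on conformational ensembles.
`allonet` implements that analysis chain end to end:

1. **Ensemble post-processing**: least-squares superposition (Kabsch, proper
   rotations only), B-factors, dynamic cross-correlation maps (DCCM),
   principal component analysis, low-frequency-mode mobility, rigid-body
   subdomain RMSD/rotation, and density-of-states population analysis.
2. **Rigidity profiling**: per-residue force constants
   $k_i = 3 k_B T / \langle (d_i - \langle d_i\rangle)^2\rangle$, where
   $d_i$ is the mean distance from residue $i$ to the rest of the protein;
   peaks mark hinge candidates.
3. **Residue interaction networks**: side-chain heavy-atom contacts within
   4.5 Å, normalized per residue type,
   $I_{ij} = n_{ij}/(N_i N_j) \times 100$, thresholded at $I_{min}$
   (default 2.5%).
4. **Dynamics-weighted centrality**: edge weights $w_{ij} = -\log|C_{ij}|$,
   all-pairs shortest paths with multiplicity counting (Floyd–Warshall),
   and betweenness normalized per connected component by $(N-1)(N-2)/2$.
5. **Communities**: hubs (degree ≥ 4), $k$-clique enumeration ($k = 3, 4$),
   clique percolation with a relaxed adjacency rule (cliques sharing $k-1$
   *or* $k-2$ nodes), and a stability filter keeping communities intact in
   more than 75% of ensemble snapshots.
6. **Residue depth vs HDX**: ensemble-averaged distance of residues below
   the solvent-accessible surface, differential (state A − state B)
   protection maps, and sign agreement with hydrogen-deuterium exchange
   peak-ratio tables.
7. **Binding energetics**: MM-GBSA-style aggregation
   $\Delta G_{bind} = \langle\Delta G_{MM}\rangle +
   \langle\Delta G_{solv}\rangle - \langle T\Delta S\rangle$ over
   per-snapshot term tables, a $\sigma \cdot SASA$ nonpolar term
   ($\sigma = 0.0072$ kcal mol$^{-1}$ Å$^{-2}$), and computational alanine
   scanning by Cβ truncation.

Because production MD trajectories are rarely shippable, the package also
contains a first-class synthetic-ensemble generator (module
`synthetic_ensembles`): an anisotropic network model (ANM) whose inverted
Hessian gives an *analytic* fluctuation covariance, plus two-state mixtures
and planted-community graphs. Every estimator in the package is validated
against these closed-form oracles.

## The synthetic generator and what it does (not) emulate

`build_toy_protein()` constructs an ideal helix or extended chain whose
residues carry pseudo side-chain heavy atoms (CB, CG, ...) fanned along the
chain axis so that side chains of neighbouring helix turns genuinely contact
within 4.5 Å. `anm_covariance()` builds the ANM Hessian on Cα nodes (cutoff
13 Å, γ = 1 kcal mol$^{-1}$ Å$^{-2}$, T = 300 K -- conventional
elastic-network settings), discards the six rigid-body modes by a relative
eigenvalue threshold of $10^{-8}$, and returns $k_B T\, H^{+}$.
`sample_gaussian_ensemble()` draws frames with exactly that covariance.

```{r anm-oracle}
toy <- build_toy_ca_trace(10, "helix")
model <- anm_covariance(toy)
ens <- sample_gaussian_ensemble(model, 5000, seed = 1)
max(abs(cross_correlation(ens) - analytic_cross_correlation(model)))
```

These fixtures reproduce the *statistics* a Gaussian ensemble should have --
they do not emulate force-field energetics, anharmonic transitions, solvent
effects, or the specific conformational cycle of any chaperone. A passing
oracle test therefore certifies the estimator, not biological realism.
Two-state mixtures (`make_two_state_ensemble()`) add the one anharmonic
feature the method's population-shift analysis needs: a bimodal ensemble
with known state labels.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| contact cutoff | 4.5 | Å | side-chain heavy-atom contact definition |
| $I_{min}$ | 2.5 | % | edge threshold; scan 1–15% with `lcc_transition_scan()` |
| hub degree | 4 | – | hub definition |
| clique sizes | 3, 4 | – | community building blocks |
| stability threshold | 0.75 | fraction | strict "more than" comparison |
| snapshots | ≤ 1000 | – | ensemble network analysis cap |
| correlation filter $c_{min}$ | 0.5 | – | correlated-intermediates band, applied to $|C|$ |
| temperature | 300 | K | force-constant conversion, $k_B = 0.0019872041$ |
| probe radius | 1.4 | Å | SASA and residue depth |
| $\sigma$ (nonpolar) | 0.0072 | kcal mol$^{-1}$ Å$^{-2}$ | $\Delta G_{np} = \sigma \cdot SASA$ |

The 20 per-type normalization factors $N_i$ are not distributed with the
method; `derive_normalization_table()` derives them from the input data (max
per-type total pair count, floored at 1) and logs the table, and a
user-supplied two-column TSV overrides it. Both the printed product
denominator $N_i \times N_j$ and the $\sqrt{N_i N_j}$ variant common in the
protein-structure-network literature are implemented; the product form is
the default, the sqrt form tends to give percentages in the classical 1–15%
working range.

## Numerical and design choices

* **Betweenness** is computed on the structure-network topology with
  dynamic weights, by dense Floyd–Warshall with shortest-path multiplicity
  counting. Path lengths are considered tied when they differ by ≤ $10^{-9}$
  relative -- multiplicity counting on real-valued weights needs an explicit
  tie rule. Normalization is per connected component ($N$ = component
  size); components smaller than 3 score 0. The printed normalization
  $(N-1)(N-2)$ cannot reach 1 with a $j<k$ sum, so the package uses
  $(N-1)(N-2)/2$, which makes a star centre score exactly 1.
* **Correlation filter**: the "correlated intermediates" rule is an edge
  pre-filter $|C_{ij}| \ge 0.5$ before pathfinding (equivalent to requiring
  every consecutive pair along a path to be correlated). A `signed = TRUE`
  switch excludes strong anti-correlations instead; the default uses $|C|$.
* **Community intactness** is edge-level: a community is intact in a
  snapshot iff every edge of every constituent clique is present. This is
  the conservative reading; re-detecting communities per snapshot would be
  laxer and is not the default.
* **Relaxed clique adjacency** applies literally at $k = 3$: sharing
  $k-2 = 1$ node chains triangles through single shared residues.
* **Superposition** uses a two-pass mean reference (fit to frame 1, average,
  refit to the mean) and proper rotations only. "Lowest-frequency modes"
  are the largest-variance principal components.
* **Density of states** histograms (default 50×50 bins) are smoothed with a
  3×3 box before 8-neighbour peak picking (threshold 10% of the maximum,
  minimum separation 3 bins); raw counts feed the nearest-peak basin
  populations. Without smoothing, Poisson noise fragments basins.
* **Residue depth** is the distance from an atom to the nearest exposed
  point of the solvent-accessible surface (deterministic Fibonacci-lattice
  sampling, 256 points/atom, probe 1.4 Å, built-in vdW radii), minus the
  atom's own accessible radius, floored at 0. Surface atoms score ~0;
  hydrogens are excluded. This is a deterministic, parameter-light proxy
  for solvation-based residue-depth methods.
* **Energetics**: the pairwise backend (LJ 12-6 + Coulomb with
  distance-dependent dielectric $\epsilon(r) = 4r$, 332.06 kcal Å mol$^{-1}$
  e$^{-2}$) is a deterministic surrogate, *not* a calibrated force field;
  generalized-Born polar solvation enters only through a pluggable hook
  (default 0) and entropy only as a user scalar. Under the single-trajectory
  protocol (no re-minimization) intramolecular terms cancel exactly, so
  absolute $\Delta G$ values are not comparable to published
  CHARMM/GB numbers -- component differences and $\Delta\Delta G$ ranks are
  the meaningful outputs. Alanine scanning is pure Cβ truncation (Cβ keeps
  its coordinates; no side-chain rebuild or minimization).
* **Zero-variance handling**: correlations 0 with a warning; force
  constants capped at $10^6$ so peak detection stays finite. Profile peaks
  require strict dominance over a ±3-residue window, at least half the
  profile maximum, and cannot sit on the profile boundary.
* **Glycine** has no side-chain heavy atoms; its Cα stands in for contact
  counting so glycines can form network edges at all.
* **All-atom force constants** share the Cα–Cα sequence-neighbour
  exclusion, which makes the CA and all-atom modes agree exactly on
  single-atom-residue toys.
* **Seeding**: every stochastic generator draws from a private stream
  seeded from (user seed, operation name), so pipeline stages are
  independently reproducible and never disturb the caller's RNG.

## Problem sizes used in the validation suite

The test suite and the acceptance script run entirely on synthetic data:
random graphs of 5–14 nodes against exhaustive path/clique enumeration
(hundreds of instances), a 20-residue ANM toy sampled at 50,000 frames for
the estimator-convergence checks (maximum DCCM error vs the analytic matrix
is typically < 0.01), 10,000-frame isotropic-jitter ensembles for the
B-factor closed form, a 2,000-frame two-state mixture at $p_A = 0.7$ for
the population-shift recovery, and ≤ 125-atom lattices for the depth/SASA
oracles. These sizes were chosen so that Monte-Carlo error is far inside
each assertion's tolerance while the whole suite stays fast.

## Worked mini-example

```{r mini, message = FALSE}
toy <- build_toy_protein(20, "helix", 3, seed = 1)
ens <- make_two_state_ensemble(toy, toy, 1, sigma = 0.25, n_frames = 50, seed = 2)
fit <- superpose_ensemble(ens)
C <- cross_correlation(fit)
norm <- derive_normalization_table(toy)
im <- interaction_strengths(toy, norm, "sqrt_product")
lcc_transition_scan(im)$transition
g <- build_graph(im, I_min = 2)
cent <- graph_betweenness(assign_edge_weights(g, C, c_min = 0.3))
head(cent[order(-cent$betweenness), ], 3)
```

## Known limitations

* No mmCIF or binary trajectory formats; convert to multi-model PDB or a
  coordinate table first.
* No time-correlation analysis or trajectory clustering.
* The energy backend is a surrogate; plug in real per-snapshot term tables
  (`snapshot_energy_table` objects) for production energetics.
* Depth is probe-based, not explicit-solvent; HDX comparison is sign-level
  only (protection thresholds 1.1 / 1.0 with the band between excluded).
* Clique percolation is exact and therefore exponential in the worst case;
  it is intended for residue graphs at realistic $I_{min}$, not dense
  graphs.
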