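# allonet

Network-centric analysis of protein conformational ensembles, aimed at the
question that drives allosteric-communication studies of multidomain
machines such as the Hsp70/Hsp110 chaperones: *which residues mediate the
coupling between distant functional sites, and through which interaction
communities does the signal travel?*

From a structural ensemble (multi-model PDB or MD-derived snapshots) the
package computes, in one chain:

* **dynamics maps** — superposition, B-factors, dynamic cross-correlation
  matrices (DCCM), PCA and low-frequency-mode mobility, rigid-body
  subdomain RMSD/rotation, density-of-states population analysis;
* **rigidity profiles** — per-residue force constants
  `k_i = 3 k_B T / Var(d_i)`, where `d_i` is the mean distance of residue
  *i* to the rest of the protein; profile peaks flag hinge candidates;
* **residue interaction networks** — side-chain heavy-atom contacts within
  4.5 Å, normalized per residue type (`I_ij = n_ij / (N_i N_j) × 100`),
  thresholded at `I_min` (default 2.5 %), with a largest-cluster transition
  scan;
* **dynamics-weighted centrality** — edge weights `w_ij = −log|C_ij|`,
  all-pairs shortest paths with multiplicity counting (Floyd–Warshall), and
  betweenness `C_b(i) = Σ_{j<k} g_jk(i)/g_jk`, normalized per connected
  component by `(N−1)(N−2)/2`, ensemble-averaged over up to 1,000 snapshot
  graphs;
* **communities** — hubs (degree ≥ 4), k-clique percolation (k = 3, 4) with
  a relaxed adjacency rule (cliques sharing k−1 *or* k−2 nodes), and a
  stability filter keeping communities intact in more than 75 % of
  snapshots;
* **residue depth vs HDX** — ensemble-averaged burial below the
  solvent-accessible surface, differential protection maps between states,
  and sign agreement against HDX peak-ratio tables (thresholds 1.1 / 1.0);
* **binding energetics** — MM-GBSA-style aggregation
  `ΔG_bind = ⟨ΔG_MM⟩ + ⟨ΔG_solv⟩ − ⟨TΔS⟩` over per-snapshot term tables,
  `ΔG_np = 0.0072 · SASA`, and computational alanine scanning by Cβ
  truncation (`ΔΔG = ΔG_mut − ΔG_WT`).

A first-class synthetic-data module supplies elastic-network (ANM)
ensembles with an *analytic* covariance, two-state population mixtures with
known labels, planted-community graphs, and toy multi-atom proteins — so
every estimator in the package is tested against a closed-form or
brute-force oracle without external data. See the methods vignette
(`vignettes/allosteric-network-analysis.Rmd`) for the model details and
design decisions.

## Worked example

Simulate a 30-residue helical toy whose Cα dynamics follow an anisotropic
network model (cutoff 9 Å), then run the network stages of the pipeline:

```r
library(allonet)
cfg <- list(
  input = list(simulate = list(n_residues = 30, geometry = "helix",
                               sidechain_atoms = 3, n_frames = 100)),
  stages = c("bfactors", "forceconst", "network", "centrality", "communities"),
  seed = 11,
  parameters = list(I_min = 2, denominator = "sqrt_product",
                    max_snapshots = 50, anm_cutoff = 9),
  output_dir = "run1")
mf <- run_pipeline(cfg)
generate_report(mf, "run1/report.txt")
```

The report (abridged) reads:

```
stage bfactors     ok
stage dccm         ok
stage forceconst   ok
stage network      ok
stage centrality   ok
stage communities  ok

hubs: none detected
I_min transition: 2%
top centrality residues:
  A:13:        0.49152
  A:18:        0.40381
  A:14:        0.32210
  A:15:        0.31333
```

Reading the numbers: the largest connected cluster of the interaction graph
collapses at `I_min = 2 %` (the scan in `lcc_scan.tsv` shows the full
curve), and the ensemble-averaged, correlation-weighted betweenness
concentrates on the middle of the helix (residues 13–18, `C_b` up to 0.49)
— the mid-chain residues sit on almost half of all correlated shortest
paths, exactly the hinge-like signature the method uses to nominate
allosteric mediator residues. Per-residue TSV profiles (B-factors, force
constants, centrality, depth) land in the output directory and round-trip
through `read_profile()`.

Every analysis is equally usable as plain functions
(`cross_correlation()`, `force_constant_profile()`,
`interaction_strengths()` → `build_graph()` → `assign_edge_weights()` →
`graph_betweenness()`, `enumerate_k_cliques()` →
`clique_percolation_communities()` → `community_stability_filter()`,
`residue_depth_profile()`, `snapshot_energy_table()` →
`mmgbsa_aggregate()`, `alanine_scan()`, …); a thin command-line wrapper
lives at `inst/scripts/allonet.R`.

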