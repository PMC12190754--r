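# EssDyn

Essential-dynamics analysis of protein molecular-dynamics trajectories in R.

MD simulations of a protein — say, three 100 ns replicas of the ~449-residue
intra-melanosomal domain of tyrosinase, snapshotted every 1 ns — yield a few
hundred frames of Calpha coordinates whose scientific content is collective:
which large-scale motions dominate, how many conformational states the
protein visits, which residue blocks move together or against each other, and
where the free-energy basins sit. EssDyn is for the structural
bioinformatician who has such trajectories (plus, optionally, per-frame
stability energies from an external calculator and a tunnel-presence table
from a tunnel detector) and wants the complete, reproducible analysis chain
behind those questions.

## What it computes

Given aligned Calpha frames `r_i(t)`, the package builds the frames × 3N
coordinate matrix (x, y, z per residue — 1347 columns for 449 residues) and:

- **Superposition** — Kabsch least squares: `R = V diag(1, 1, det(VUᵀ)) Uᵀ`
  from the SVD of the cross-covariance, the proper rotation minimizing RMSD.
- **Essential dynamics** — PCA of the column correlation (default) or
  covariance matrix; loadings are unit eigenvectors, score variances equal
  eigenvalues; Horn's parallel analysis (permutation variant, 95th
  percentile, 100 draws) decides how many components survive.
- **Conformational states** — K-means on the PC1/PC2 scores with a
  silhouette scan over k = 2..10; states map to 0-based frame ranges with
  (replica, time) labels. Loading-selection rules: |loading| ≥ 0.7 on any
  kept component, or the top 10% per loading-space cluster by distance from
  the origin.
- **Coordinated motion** — DCCM
  `C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)` in [−1, +1], block
  summaries, and porcupine arrow fields from any eigenvector (BILD/CSV
  export).
- **Descriptors** — per-residue RMSF (per-replica-combined or global),
  radius of gyration, Shrake–Rupley SASA on a 960-point Fibonacci lattice.
- **Stability** — free-energy landscape: per-frame ΔG interpolated linearly
  over the Delaunay triangulation of the (PC1, PC2) scores onto a 100 × 100
  grid, minima extracted by topographic persistence; descriptive-statistics
  tables; and the pooled two-proportion Z-test
  `z = (p₂ − p₁)/√(p̂(1 − p̂)(1/n₁ + 1/n₂))` for tunnel presence.
- **Synthetic ground truth** — a generator planting known collective modes,
  per-replica basins, block correlations, rigid-body nuisance and energy
  minima, so every stage is testable without MD.

## Worked example

```r
library(EssDyn)

spec <- syntheticSpec(seed = 42)          # 449 residues, 3 x 101 frames
sim  <- generateSynthetic(spec)

al  <- superposeTrajectory(sim$trajectory)
cm  <- standardizeColumns(buildCoordinateMatrix(al))
pa  <- parallelAnalysis(cm, seed = 42)
pa
#> ParallelAnalysisResult ( permutation ): 2 components retained
#>   observed: 391.467, 262.123,   5.563,   5.232,   5.201 ...
#>   noise 95th pct: 9.804, 9.510, 9.394, 9.276, 9.177 ...

res <- retainComponents(essentialDynamics(cm), pa@kRetained)
screeData(res, 3)
#>   component eigenvalue proportion_pct cumulative_pct
#> 1       PC1  391.46666      29.062113       29.06211
#> 2       PC2  262.12266      19.459737       48.52185
#> 3       PC3    5.56346       0.413026       48.93488

silhouetteScan(res, seed = 42)
#> ClusterModel: k = 3 | mean silhouette = 0.812
#>   cluster sizes: 101, 101, 101

tunnelPresenceTest(sim$tunnelTable)
#> Two-proportion Z-test
#>   group 1: 21/60 (0.35)  group 2: 45/60 (0.75)
#>   pooled 0.55  se 0.0908  z 4.404  p (two-sided) 0.0000
```

Reading the output: the two basin-separating components dominate the
correlation spectrum (eigenvalues 391 and 262 against a noise threshold near
10, together 48.5% of total variance), the silhouette scan recovers the three
planted conformational basins — one per replica, 101 frames each — and the
tunnel table's presence counts for this seed (21/60 vs 45/60) give a strongly
significant pooled z of 4.40. On the reference counts 23/60 vs 38/60,
`twoProportionZTest(23, 60, 38, 60)` prints pooled 0.51, |z| 2.74,
p 0.0062.

The one-call version of the same chain, writing every table (RMSF, Rg,
scree, scores/loadings, cluster runs, selections, DCCM, porcupine, landscape,
Z-test) plus a resolved-config JSON and log into an output directory:

```r
en  <- cbind(sim$energy@frameLabels, dG_kJ_per_mol = sim$energy@dG)
run <- runPipeline(runConfig(sim$trajectory, energy = en,
                             tunnel = sim$tunnelTable,
                             outdir = "run1", seed = 42))
pipelineReport(run$dir)                   # plain-text summary report
```

## Acceptance script

`scripts/acceptance.R` regenerates the default synthetic world under the
given seed, runs the full pipeline on it end to end (alignment, descriptors,
PCA with parallel analysis, clustering, loading selections, DCCM, porcupine,
landscape, Z-test, report), and writes its JSON result to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
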