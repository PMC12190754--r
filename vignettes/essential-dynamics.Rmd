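---
title: "Essential dynamics of Calpha trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Essential dynamics of Calpha trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EssDyn)
```

## The problem

Molecular-dynamics simulations of a protein produce thousands of coordinate
snapshots whose interesting content — large-scale collective motions,
conformational states, coordinated residue blocks, energy basins — is buried
in 3N-dimensional noise. *Essential dynamics* extracts that content by
principal component analysis of the Calpha coordinate fluctuations. EssDyn
implements the full desk-side analysis chain for this kind of data:

1. read multi-model PDB trajectories, concatenate replicas, and superpose
   every frame onto a reference (Kabsch least squares);
2. per-residue / per-frame descriptors: RMSF, radius of gyration,
   Shrake–Rupley SASA;
3. PCA of the frames × 3N coordinate matrix, with Horn's parallel analysis to
   decide how many components to keep;
4. K-means clustering of the PC scores with a silhouette scan over k, mapping
   conformational states to (replica, time) ranges;
5. two loading-selection rules that name the residues driving each component;
6. the dynamic cross-correlation matrix (DCCM) and porcupine vector fields;
7. a free-energy landscape over the PC1/PC2 plane from a per-frame energy
   series, and a pooled two-proportion Z-test for tunnel presence between two
   structure groups.

The typical subject is a single-domain protein such as the ~449-residue
intra-melanosomal domain of tyrosinase, simulated in triplicate for 100 ns
with snapshots every 1 ns: 3 × 101 = 303 frames of 449 residues, giving a
303 × 1347 coordinate matrix. Those numbers are the package defaults
throughout, but every size is an argument.

## Coordinate matrix and superposition

All analyses run on Calpha positions. Frames are superposed one by one onto a
reference frame (default: the first frame of the first replica; any frame or
an external structure can be supplied) by the Kabsch algorithm: SVD of the
3 × 3 cross-covariance with a determinant correction so the fit is a proper
rotation. Superposition strictly minimizes RMSD, so per-frame RMSD to the
reference never increases — a property the tests exercise on random data.
Collinear point sets make the optimal rotation non-unique; the fit proceeds
with a warning rather than failing, since a real Calpha trace is never
collinear.

The coordinate matrix stores one row per frame and columns x, y, z per
residue in ascending residue order. Row `r` reshaped to N × 3 is exactly
frame `r`; building the matrix from a trajectory without alignment provenance
warns (rigid-body motion would masquerade as internal motion) but is allowed,
because the warning case is sometimes wanted for diagnosis.

## PCA, standardization, and component retention

The default PCA basis is the **correlation matrix**: columns are centered and
scaled to unit sample variance before decomposition. Standardizing
coordinates is unusual in the MD literature (classical essential dynamics
decomposes the covariance), but it is what a GUI statistics tool applies when
asked to "standardize and analyze", and it is therefore the default here;
covariance-basis PCA is one flag away and is what the planted-variance
recovery tests use, since planted mode variances are only meaningful in the
unscaled basis. Zero-variance columns are left at zero and flagged rather
than producing NaNs.

The decomposition itself is a thin SVD of the centered data — numerically
preferable to forming the 3N × 3N covariance, and automatically efficient on
both the 303 × 1347 default shape and small test matrices. Loadings are
unit-norm eigenvectors; scores are projections of the centered data, so score
variances equal eigenvalues. Eigenvector signs are arbitrary, so each loading
column is flipped to make its largest-magnitude entry positive; output is
then deterministic across eigensolvers.

**Component retention** uses Horn's parallel analysis in its permutation
variant: each of `nDraws` (default 100) noise replicates permutes every
column independently, preserving marginals while destroying correlation. The
per-component noise threshold is the conservative order statistic
`sort(noise)[ceiling((nDraws + 1) * percentile)]` at the 95th percentile, and
components are retained while the observed eigenvalue exceeds the threshold,
stopping at the first failure. A Monte-Carlo variant (iid standard-normal
draws) is available; permutation is the default because it makes no
distributional assumption. Whether the original GUI used permutation or
normal draws is not determinable, which is exactly why both are implemented
and the choice is logged.

One statistical fact matters for testing: on pure iid noise the observed
matrix is exchangeable with its column permutations, so the probability that
no component is retained is pinned near the percentile itself (~0.95). Claims
of the form "k = 0 in ≥ 95% of runs" are therefore evaluated over fixed,
pre-declared seed panels — the result is deterministic for the shipped
implementation — rather than re-randomized per run.

## Conformational states and loading selection

The silhouette scan fits K-means (25 restarts per k, seeded) for each k in
2..10 on the PC1/PC2 score plane — the third component is excluded by default
because in this data regime its variation adds little; the dimension is an
argument. The returned model maximizes mean silhouette width, the full
silhouette-by-k table is kept for audit, and a model whose best mean
silhouette is below 0.4 carries a `noStrongStructure` flag instead of
pretending states exist. Cluster labels are 0-based and mapped to contiguous
0-based frame-index runs with (replica, time) labels, because in triplicate
MD data conformational states tend to coincide with replicas.

Two selection rules name the variables (residue × axis) behind the leading
components:

- **threshold**: select every variable with |loading| ≥ 0.7 on any considered
  component; the bound is inclusive.
- **top decile**: cluster the PC1/PC2 loading points by K-means with k equal
  to the score-space cluster count, rank each cluster's variables by
  Euclidean distance from the origin of the loading plane, and keep the top
  10% — at least ⌈0.10 · cluster size⌉, with all boundary ties included.
  Over-selection on ties was chosen over arbitrary dropping: determinism
  without a hidden sort order.

## DCCM and porcupine fields

The DCCM entry for residues i, j is the time-averaged dot product of their
centered displacement vectors, normalized by the root product of their mean
squared displacements, hence in [−1, +1] with +1 on the diagonal. Immobile
residues (zero displacement variance) get zero off-diagonal entries and are
flagged. The matrix equals the normalized residue-block trace of the 3N
covariance, a cross-check the tests perform against the PCA module on the
same input. The block summarizer segments the chain into maximal runs of
consecutively coupled residues (C[i, i+1] ≥ threshold, runs of length ≥ 2)
and reports every segment pair whose mean correlation exceeds the threshold
in magnitude, signed — a deliberately simple, testable rendering of
"residues A–B move with/against residues C–D".

A porcupine field turns one eigenvector into one arrow per residue (the
x, y, z loading triplet), anchored at the reference Calpha. The default scale
makes the longest arrow 10 Å — the source material never states its scale, so
a visually useful one was fixed and recorded. Fields export to BILD (for
molecular viewers) or CSV; two variants' fields over a common reference
reduce to a per-residue arrow-difference table, which is the testable form of
a superimposed porcupine comparison.

## Free-energy landscape

Per-frame energies (an external input: this package does not compute folding
free energies) are interpolated over the PC1/PC2 score plane piecewise
linearly on a Delaunay triangulation onto a regular 100 × 100 grid. Grid
nodes outside the convex hull of the scores stay undefined — no extrapolated
minima are invented — and the interpolant reproduces the input values at the
data points exactly. A density-based alternative (−kT·ln of a 2-D histogram
density) is easy to build from the same scores but is *not* what this
analysis chain plots, so it is not the default anywhere.

Minima are extracted by 0-dimensional persistence (watershed flooding) rather
than raw 8-neighbour grid minima, because a piecewise-linear interpolant
grows micro-dips along basin ridges wherever the triangulation crosses the
ridge. A basin must be at least 1% of the defined energy range deeper than
its escape saddle to count (the deepest basin always survives); the threshold
is an argument in kJ/mol. A related resolution fact, verified in the tests:
for a convex basin the interpolant's minimum sits at the *sample* nearest the
basin center, so minima are localized to one grid spacing around the best
sample, not around the analytic center — sampling density, not grid
resolution, is the limit.

The pooled two-proportion Z-test compares tunnel-presence frequencies between
two structure groups: z = (p₂ − p₁)/√(p̂(1 − p̂)(1/n₁ + 1/n₂)) with pooled
p̂, two-sided normal p-value, no continuity correction. On the reference
counts 23/60 vs 38/60 this yields |z| = 2.74 and p = 0.0062 — this exact
formulation was chosen because it reproduces those printed values.

## The synthetic world

Every pipeline stage is validated against a generator with known ground
truth, because real 100-ns trajectories are neither shippable nor
deterministic. The generator's defaults state one world:

- a 449-residue Calpha chain (ideal helix, exact 3.8 Å spacing, seeded
  orientation), 3 replicas × 101 frames at 1 ns;
- three orthonormal collective modes with amplitude variances 9, 4, 1 Ų —
  a clearly separated spectrum a scree plot would keep; mode 1 carries an
  anti-correlated two-block displacement pattern for the DCCM checks;
- one conformational basin per replica: per-replica amplitude means at
  120° spacing, radius 15, in the (mode 1, mode 2) plane — roughly 5–7
  within-basin standard deviations apart, the "well-separated clusters that
  coincide with trajectories" regime;
- isotropic per-atom coordinate noise of 0.3 Å, and a random rigid
  rotation/translation per frame (the nuisance superposition must remove —
  tests compare nuisance-on and nuisance-off runs after alignment);
- energies dG(t) = 95 + depth(replica) + Σ w_k (a_k − mean_k)² + N(0, 3²)
  kJ/mol with depths 0/8/16 and w = 0.08 on modes 1–2: minima at the basin
  centers, overall range on the order of the reference descriptive table;
- a tunnel table sampling every 5th ns (excluding 0 ns: 60 frames per group)
  with presence probabilities 23/60 and 38/60.

The manifest records every latent draw (amplitudes, modes, rigid transforms,
energy parameters), so tests assert recovery rather than plausibility. What
the generator does *not* emulate: force-field physics, solvent, anharmonic
basins, kinetic ordering of states within a replica — so a green suite
establishes that the *analysis* is correct on data with this statistical
shape, not that any particular protein behaves this way.

One derived correction worth recording: at the planted tunnel probabilities
the pooled z-test has power ≈ 0.56 at α = 0.01 (and ≈ 0.80 at α = 0.05) for
60 frames per group — a 200,000-replicate simulation, frozen into the tests
as a frequency band over a fixed seed panel. A single synthetic run is
therefore *not* guaranteed a p below 0.01, and the pipeline reports whatever
the data give.

## Numerical choices and degenerate inputs

- Rotation orthonormality is enforced to 1e-8; reconstruction and
  orthogonality invariants to 1e-8–1e-12 depending on conditioning.
- PDB coordinates are fixed-width %8.3f: round-trips are exact to 0.001 Å,
  and magnitudes above 9999.999 Å are a format-overflow error, not silent
  truncation.
- Single-frame trajectories have no defined variance: RMSF errors rather
  than returning zeros.
- Constant columns standardize to zero with a flag; immobile residues get
  zero DCCM rows with a flag; a pooled proportion of 0 or 1 makes the Z-test
  degenerate and is an error.
- K-means uses 25 restarts under a logged seed; empty-cluster restarts are
  handled by `stats::kmeans` itself. All stochastic stages take explicit
  seeds and two runs with the same configuration produce byte-identical
  output files.
- Timestamp conventions: global frame indices are 0-based everywhere; tables
  print both the index and (replica, time_ns), so no downstream reader needs
  to guess.

## Limitations

- SASA uses a Fibonacci lattice of 960 points and a built-in radius table
  (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2 Å): reproducible, ~1% quadrature
  accuracy on spheres, but not numerically identical to any particular MD
  engine's macro — absolute SASA/Rg magnitudes from such engines are not
  reproduction targets.
- Eigenvalue tables from unavailable MD trajectories cannot be reproduced;
  only their schema is.
- The landscape is an interpolation of supplied energies, not a Boltzmann
  inversion of sampling density; the two differ whenever sampling is not
  equilibrium-weighted.
- Binary trajectory formats (xtc/dcd) are out of scope; convert externally
  to multi-model PDB or the CSV coordinate-matrix dialect.
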