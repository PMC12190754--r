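Package: EssDyn
Title: Essential Dynamics of Protein Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Essential-dynamics analysis of Calpha coordinate trajectories from
    molecular dynamics simulations. Provides multi-model PDB trajectory input and
    output, replica concatenation, Kabsch least-squares superposition, per-residue
    and per-frame structural descriptors (RMSF, radius of gyration, Shrake-Rupley
    solvent-accessible surface area), standardized principal component analysis
    with Horn's parallel analysis for component retention, silhouette-scanned
    K-means clustering of conformational states, loading selection rules, dynamic
    cross-correlation matrices, porcupine vector fields, free-energy landscapes
    over the principal-component plane, a two-proportion Z-test for tunnel
    presence, and a synthetic trajectory generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, graphics, cluster, interp, jsonlite, withr
Suggests: testthat (>= 3.0.0), clue
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'trajectory-core.R'
    'superpose.R'
    'coordinate-matrix.R'
    'descriptors.R'
    'essential-dynamics.R'
    'conformational-clustering.R'
    'coordinated-motion.R'
    'stability-landscape.R'
    'synthetic-data.R'
    'pipeline.R'
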