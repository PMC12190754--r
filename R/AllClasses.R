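#' @import methods
NULL

## Central containers for Calpha essential-dynamics analysis. Coordinates are
## stored as an n_frames x n_residues x 3 array in Angstrom; frame metadata
## (replica id, snapshot time) travels alongside so that every downstream
## table can be labelled (replica, time_ns).

#' Frame: a single snapshot of Calpha positions
#'
#' One trajectory snapshot. `coords` is an N x 3 matrix of Calpha positions in
#' Angstrom, one row per residue in ascending residue order.
#'
#' @slot coords numeric matrix, N x 3 (Angstrom).
#' @slot residueIndex integer vector, strictly increasing 1-based residue numbers.
#' @slot residueName character vector of 3-letter residue codes.
#' @slot element character vector of element symbols (Calpha traces: "C").
#' @slot timeNs snapshot time in nanoseconds.
#' @slot replicaId replica label (small integer).
#' @exportClass Frame
setClass("Frame",
  representation(
    coords = "matrix",
    residueIndex = "integer",
    residueName = "character",
    element = "character",
    timeNs = "numeric",
    replicaId = "integer"
  ),
  prototype(timeNs = 0, replicaId = 1L)
)

setValidity("Frame", function(object) {
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3L) return("coords must have 3 columns (x, y, z)")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (length(object@residueIndex) != n) return("residueIndex length != number of atoms")
  if (n > 1L && any(diff(object@residueIndex) <= 0L))
    return("residueIndex must be strictly increasing")
  if (length(object@residueName) != n) return("residueName length != number of atoms")
  if (length(object@element) != n) return("element length != number of atoms")
  TRUE
})

#' Trajectory: ordered Calpha snapshots across replicas
#'
#' Frames are stored as an `n_frames x n_residues x 3` array; all frames share
#' one residue set. Frame order is (replicaId ascending, timeNs ascending) and
#' the global frame index is 0-based in all reports.
#'
#' @slot coords numeric array, n_frames x n_residues x 3 (Angstrom).
#' @slot residueIndex,residueName,element per-residue annotation (shared by all frames).
#' @slot replicaId integer vector, one entry per frame.
#' @slot timeNs numeric vector, one entry per frame (ns).
#' @slot snapshotIntervalNs snapshot spacing in ns (default 1).
#' @slot aligned logical provenance flag: TRUE after [superposeTrajectory()].
#' @slot referenceLabel free-text provenance of the alignment reference.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    coords = "array",
    residueIndex = "integer",
    residueName = "character",
    element = "character",
    replicaId = "integer",
    timeNs = "numeric",
    snapshotIntervalNs = "numeric",
    aligned = "logical",
    referenceLabel = "character"
  ),
  prototype(snapshotIntervalNs = 1, aligned = FALSE, referenceLabel = NA_character_)
)

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be an n_frames x n_residues x 3 array")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  nf <- d[1]; nr <- d[2]
  if (length(object@residueIndex) != nr) return("residueIndex length != n_residues")
  if (nr > 1L && any(diff(object@residueIndex) <= 0L))
    return("residueIndex must be strictly increasing (one Calpha per residue)")
  if (length(object@replicaId) != nf) return("replicaId length != n_frames")
  if (length(object@timeNs) != nf) return("timeNs length != n_frames")
  if (any(object@timeNs < 0)) return("timeNs must be non-negative")
  ord <- order(object@replicaId, object@timeNs)
  if (!identical(ord, seq_len(nf)))
    return("frames must be ordered by (replicaId, timeNs)")
  if (object@snapshotIntervalNs <= 0) return("snapshotIntervalNs must be positive")
  TRUE
})

#' CoordinateMatrix: frames x 3N table of aligned Calpha coordinates
#'
#' The PCA substrate. Columns are ordered x, y, z per residue with residues
#' ascending, so 449 residues yield 1347 columns; rows carry (replica, time)
#' labels. `standardized` marks column-wise z-scoring; `centers`/`scales` allow
#' exact back-transformation. `zeroVariance` flags constant columns that were
#' left at zero by standardization.
#'
#' @slot values numeric matrix, n_frames x 3N.
#' @slot columnLabels data.frame with columns residue_index, axis.
#' @slot frameLabels data.frame with columns replica_id, time_ns.
#' @slot standardized logical.
#' @slot centers,scales per-column mean and sd recorded by [standardizeColumns()].
#' @slot zeroVariance integer indices of constant columns.
#' @slot aligned logical provenance flag inherited from the trajectory.
#' @exportClass CoordinateMatrix
setClass("CoordinateMatrix",
  representation(
    values = "matrix",
    columnLabels = "data.frame",
    frameLabels = "data.frame",
    standardized = "logical",
    centers = "numeric",
    scales = "numeric",
    zeroVariance = "integer",
    aligned = "logical"
  ),
  prototype(standardized = FALSE, centers = numeric(0), scales = numeric(0),
            zeroVariance = integer(0), aligned = FALSE)
)

setValidity("CoordinateMatrix", function(object) {
  if (ncol(object@values) %% 3L != 0L) return("column count must be a multiple of 3")
  if (nrow(object@columnLabels) != ncol(object@values))
    return("columnLabels rows != columns")
  if (nrow(object@frameLabels) != nrow(object@values))
    return("frameLabels rows != rows")
  if (!all(c("residue_index", "axis") %in% names(object@columnLabels)))
    return("columnLabels needs residue_index and axis")
  if (!all(c("replica_id", "time_ns") %in% names(object@frameLabels)))
    return("frameLabels needs replica_id and time_ns")
  TRUE
})

#' EssentialDynamicsResult: spectrum, scores and loadings of a coordinate PCA
#'
#' @slot eigenvalues descending non-negative eigenvalues of the column
#'   covariance (correlation when standardized).
#' @slot varianceProportion,cumulativeProportion proportions in [0, 1].
#' @slot scores n_frames x k matrix of frame projections.
#' @slot loadings 3N x k matrix of unit-norm eigenvectors, sign-fixed so the
#'   largest-magnitude entry of each column is positive.
#' @slot kRetained retained-component count (all components until a retention
#'   rule such as [parallelAnalysis()] is applied).
#' @slot standardized whether the input was column-standardized.
#' @slot columnLabels,frameLabels labels carried from the CoordinateMatrix.
#' @exportClass EssentialDynamicsResult
setClass("EssentialDynamicsResult",
  representation(
    eigenvalues = "numeric",
    varianceProportion = "numeric",
    cumulativeProportion = "numeric",
    scores = "matrix",
    loadings = "matrix",
    kRetained = "integer",
    standardized = "logical",
    columnLabels = "data.frame",
    frameLabels = "data.frame"
  )
)

setValidity("EssentialDynamicsResult", function(object) {
  ev <- object@eigenvalues
  if (any(ev < -1e-9)) return("eigenvalues must be non-negative")
  if (is.unsorted(rev(ev), strictly = FALSE)) return("eigenvalues must be descending")
  if (abs(sum(object@varianceProportion) - 1) > 1e-9)
    return("variance proportions must sum to 1")
  if (any(diff(object@cumulativeProportion) < -1e-12))
    return("cumulative proportion must be non-decreasing")
  if (object@kRetained < 1L) return("kRetained must be positive")
  TRUE
})

#' ParallelAnalysisResult: Horn's parallel-analysis retention decision
#'
#' @slot observedEigenvalues observed spectrum.
#' @slot noisePercentiles per-component noise-eigenvalue percentiles.
#' @slot kRetained number of leading components with observed > noise percentile.
#' @slot nDraws,percentile,seed,method the knobs used ("permutation" or "normal").
#' @exportClass ParallelAnalysisResult
setClass("ParallelAnalysisResult",
  representation(
    observedEigenvalues = "numeric",
    noisePercentiles = "numeric",
    kRetained = "integer",
    nDraws = "integer",
    percentile = "numeric",
    seed = "integer",
    method = "character"
  )
)

setValidity("ParallelAnalysisResult", function(object) {
  if (length(object@noisePercentiles) != length(object@observedEigenvalues))
    return("noisePercentiles length != observedEigenvalues length")
  exceed <- object@observedEigenvalues > object@noisePercentiles
  k <- if (all(exceed)) length(exceed) else which(!exceed)[1] - 1L
  if (object@kRetained != k)
    return("kRetained must equal the count of leading components exceeding noise")
  if (object@percentile <= 0 || object@percentile >= 1)
    return("percentile must be in (0, 1)")
  TRUE
})

#' ClusterModel: silhouette-selected K-means conformational states
#'
#' Cluster labels are 0-based (0..k-1). `silhouetteByK` retains the full scan
#' so the k decision is auditable; `noStrongStructure` is TRUE when no k in the
#' scan reached mean silhouette 0.4.
#'
#' @slot k chosen number of clusters.
#' @slot labels integer vector of per-frame cluster ids in 0..k-1.
#' @slot centers k x d matrix of cluster centers in score space.
#' @slot meanSilhouette mean silhouette width of the chosen model.
#' @slot silhouetteByK data.frame (k, mean_silhouette).
#' @slot seed RNG seed used for the K-means restarts.
#' @slot noStrongStructure logical flag.
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(
    k = "integer",
    labels = "integer",
    centers = "matrix",
    meanSilhouette = "numeric",
    silhouetteByK = "data.frame",
    seed = "integer",
    noStrongStructure = "logical"
  )
)

setValidity("ClusterModel", function(object) {
  if (object@k < 2L) return("k must be >= 2")
  if (any(object@labels < 0L) || any(object@labels >= object@k))
    return("labels must lie in 0..k-1")
  if (length(unique(object@labels)) != object@k) return("every cluster must be non-empty")
  if (object@meanSilhouette < -1 || object@meanSilhouette > 1)
    return("mean silhouette must lie in [-1, 1]")
  TRUE
})

#' LoadingSelection: variables picked by a loading-selection rule
#'
#' @slot method "threshold" (|loading| >= cutoff on any considered component)
#'   or "top_decile" (top fraction by Euclidean distance from the origin of the
#'   loading plane, per loading-space cluster, boundary ties included).
#' @slot variables data.frame of the selected variables: residue_index, axis,
#'   one column per considered component, distance, and (top-decile) cluster.
#' @slot perCluster named list mapping cluster id to its selected variables.
#' @slot cutoff the threshold or fraction used.
#' @slot tieNote character: describes boundary ties, if any.
#' @exportClass LoadingSelection
setClass("LoadingSelection",
  representation(
    method = "character",
    variables = "data.frame",
    perCluster = "list",
    cutoff = "numeric",
    tieNote = "character"
  ),
  prototype(tieNote = character(0))
)

#' DCCMatrix: residue-residue dynamic cross-correlation
#'
#' Normalized covariance of per-residue displacement vectors, +1 for in-phase
#' and -1 for anti-phase motion. Residues with zero displacement variance get
#' zero off-diagonal entries and are listed in `zeroVarianceResidues`.
#'
#' @slot values symmetric N x N matrix in [-1, 1], unit diagonal.
#' @slot residueLabels residue indices.
#' @slot zeroVarianceResidues indices of immobile residues.
#' @exportClass DCCMatrix
setClass("DCCMatrix",
  representation(
    values = "matrix",
    residueLabels = "integer",
    zeroVarianceResidues = "integer"
  ),
  prototype(zeroVarianceResidues = integer(0))
)

setValidity("DCCMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (max(abs(v - t(v))) > 1e-12) return("matrix must be symmetric within 1e-12")
  if (max(abs(diag(v) - 1)) > 1e-9) return("diagonal must be 1 within 1e-9")
  if (any(v < -1 - 1e-9) || any(v > 1 + 1e-9)) return("entries must lie in [-1, 1]")
  if (length(object@residueLabels) != nrow(v)) return("residueLabels length != N")
  TRUE
})

#' PorcupineField: one displacement arrow per residue from a PC eigenvector
#'
#' @slot base N x 3 matrix of reference Calpha positions (Angstrom).
#' @slot arrows N x 3 matrix: scale x the (x, y, z) loading triplet per residue.
#' @slot magnitude per-residue arrow length |arrow|.
#' @slot component which principal component the field depicts.
#' @slot scale the multiplier applied to the eigenvector.
#' @slot residueIndex residue numbers.
#' @exportClass PorcupineField
setClass("PorcupineField",
  representation(
    base = "matrix",
    arrows = "matrix",
    magnitude = "numeric",
    component = "integer",
    scale = "numeric",
    residueIndex = "integer"
  )
)

setValidity("PorcupineField", function(object) {
  if (!identical(dim(object@base), dim(object@arrows)))
    return("base and arrows must have identical dimensions")
  if (max(abs(object@magnitude - sqrt(rowSums(object@arrows^2)))) > 1e-9)
    return("magnitude must equal |arrow| per residue")
  if (object@scale <= 0) return("scale must be positive")
  TRUE
})

#' EnergySeries: per-frame free-energy values aligned to a trajectory
#'
#' @slot frameLabels data.frame (replica_id, time_ns), one row per frame.
#' @slot dG numeric vector, kJ/mol.
#' @exportClass EnergySeries
setClass("EnergySeries",
  representation(frameLabels = "data.frame", dG = "numeric")
)

setValidity("EnergySeries", function(object) {
  if (nrow(object@frameLabels) != length(object@dG))
    return("one dG value per frame required")
  if (!all(is.finite(object@dG))) return("dG values must be finite")
  TRUE
})

#' FreeEnergyLandscape: gridded free energy over the PC1/PC2 plane
#'
#' Piecewise-linear interpolation of per-frame dG onto a regular grid; nodes
#' outside the convex hull of the observed scores are NA (undefined).
#'
#' @slot gridPC1,gridPC2 monotone grid coordinate vectors.
#' @slot dGGrid matrix (length(gridPC1) x length(gridPC2)), kJ/mol, NA outside
#'   the data support.
#' @slot stats list of descriptive statistics (overall, per replica, per cluster).
#' @slot points data.frame of the input (pc1, pc2, dG) support.
#' @exportClass FreeEnergyLandscape
setClass("FreeEnergyLandscape",
  representation(
    gridPC1 = "numeric",
    gridPC2 = "numeric",
    dGGrid = "matrix",
    stats = "list",
    points = "data.frame"
  )
)

setValidity("FreeEnergyLandscape", function(object) {
  if (is.unsorted(object@gridPC1) || is.unsorted(object@gridPC2))
    return("grid coordinate vectors must be monotone increasing")
  if (!identical(dim(object@dGGrid),
                 c(length(object@gridPC1), length(object@gridPC2))))
    return("dGGrid dimensions must match grid vectors")
  TRUE
})

#' ProportionTest: pooled two-proportion Z-test
#'
#' @slot successes1,n1,successes2,n2 counts.
#' @slot p1,p2,pooled proportions.
#' @slot se pooled standard error.
#' @slot z test statistic (p2 - p1) / se.
#' @slot pTwoSided two-sided normal p-value.
#' @exportClass ProportionTest
setClass("ProportionTest",
  representation(
    successes1 = "integer", n1 = "integer",
    successes2 = "integer", n2 = "integer",
    p1 = "numeric", p2 = "numeric", pooled = "numeric",
    se = "numeric", z = "numeric", pTwoSided = "numeric"
  )
)

setValidity("ProportionTest", function(object) {
  if (abs(object@pooled -
          (object@successes1 + object@successes2) / (object@n1 + object@n2)) > 1e-12)
    return("pooled must equal (s1+s2)/(n1+n2)")
  if (abs(object@pTwoSided - 2 * (1 - stats::pnorm(abs(object@z)))) > 1e-12)
    return("pTwoSided must equal 2*(1 - Phi(|z|))")
  TRUE
})

#' SyntheticSpec: the stated world of the synthetic trajectory generator
#'
#' Defaults mirror the emulated data regime: a 449-residue chain, 3 replicas of
#' 101 snapshots (0-100 ns at 1 ns), three dominant collective modes, one
#' conformational basin per replica, rigid-body nuisance motion, an energy
#' surface with minima at the basin centers, and tunnel-presence probabilities
#' 23/60 vs 38/60 sampled every 5 ns.
#'
#' @slot nResidues,nReplicas,framesPerReplica chain and sampling geometry.
#' @slot modeVariances per-mode amplitude variances (descending).
#' @slot modeBlocks optional list (one per mode) of data.frames
#'   (from, to, sign) planting block-correlated displacement structure.
#' @slot basinMeans nReplicas x nModes matrix of per-replica amplitude means.
#' @slot noiseSd isotropic per-atom positional noise sd (Angstrom).
#' @slot rigidNuisance apply a random rigid transform per frame.
#' @slot energyBaseline,energyDepths,energyWeights,energyNoiseSd energy model:
#'   dG(t) = baseline + depth[replica] + sum_k w_k (a_k - mean_k)^2 + noise.
#' @slot tunnelProbs tunnel-presence probability per group (length 2).
#' @slot tunnelEveryNs sampling stride of the tunnel table (ns).
#' @slot seed RNG seed.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
  representation(
    nResidues = "integer",
    nReplicas = "integer",
    framesPerReplica = "integer",
    modeVariances = "numeric",
    modeBlocks = "list",
    basinMeans = "matrix",
    noiseSd = "numeric",
    rigidNuisance = "logical",
    energyBaseline = "numeric",
    energyDepths = "numeric",
    energyWeights = "numeric",
    energyNoiseSd = "numeric",
    tunnelProbs = "numeric",
    tunnelEveryNs = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  if (object@nResidues < 3L) return("nResidues must be >= 3")
  if (is.unsorted(rev(object@modeVariances))) return("mode variances must be descending")
  if (any(object@modeVariances <= 0)) return("mode variances must be positive")
  if (!identical(dim(object@basinMeans),
                 c(object@nReplicas, length(object@modeVariances))))
    return("basinMeans must be nReplicas x nModes")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  if (length(object@tunnelProbs) != 2L ||
      any(object@tunnelProbs < 0) || any(object@tunnelProbs > 1))
    return("tunnelProbs must be two probabilities in [0, 1]")
  if (length(object@energyDepths) != object@nReplicas)
    return("energyDepths must have one entry per replica")
  if (length(object@energyWeights) != length(object@modeVariances))
    return("energyWeights must have one entry per mode")
  TRUE
})
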