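#' Silhouette-scanned K-means clustering of PC scores
#'
#' Fits K-means (Euclidean, k-means++-style multiple restarts via
#' `stats::kmeans(nstart = nInit)`) for every k in `kRange` on the first `d`
#' score columns and returns the model with the highest mean silhouette width
#' ([cluster::silhouette()]). The full silhouette-by-k table is retained. When
#' no k reaches mean silhouette 0.4 the model is flagged `noStrongStructure`.
#' Deterministic under `seed`.
#'
#' @param scores matrix of PC scores (frames x components) or an
#'   [EssentialDynamicsResult-class].
#' @param kRange candidate cluster counts (default 2:10).
#' @param d score-space dimension used for clustering (default 2: the PC1/PC2
#'   plane).
#' @param nInit K-means restarts per k (default 25).
#' @param seed RNG seed.
#' @return A [ClusterModel-class] with 0-based labels.
#' @export
silhouetteScan <- function(scores, kRange = 2:10, d = 2, nInit = 25, seed = 1) {
  if (is(scores, "EssentialDynamicsResult")) scores <- scores@scores
  scores <- as.matrix(scores)[, seq_len(min(d, ncol(scores))), drop = FALSE]
  n <- nrow(scores)
  kRange <- kRange[kRange >= 2 & kRange <= n - 1L]
  if (length(kRange) == 0L || n < max(kRange) + 1L)
    stop("need at least max(kRange) + 1 frames to scan clusters")
  dists <- stats::dist(scores)
  fits <- withr::with_seed(as.integer(seed), {
    lapply(kRange, function(k) {
      fit <- stats::kmeans(scores, centers = k, nstart = nInit, iter.max = 100)
      sil <- cluster::silhouette(fit$cluster, dists)
      list(fit = fit, meanSil = mean(sil[, "sil_width"]))
    })
  })
  silByK <- data.frame(k = kRange,
                       mean_silhouette = vapply(fits, `[[`, numeric(1), "meanSil"))
  best <- which.max(silByK$mean_silhouette)
  fit <- fits[[best]]$fit
  new("ClusterModel",
      k = as.integer(kRange[best]),
      labels = as.integer(fit$cluster - 1L),
      centers = fit$centers,
      meanSilhouette = silByK$mean_silhouette[best],
      silhouetteByK = silByK,
      seed = as.integer(seed),
      noStrongStructure = max(silByK$mean_silhouette) < 0.4)
}

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel: k =", object@k,
      "| mean silhouette =", format(object@meanSilhouette, digits = 3), "\n")
  cat("  cluster sizes:", paste(tabulate(object@labels + 1L, object@k),
                                collapse = ", "), "\n")
  if (object@noStrongStructure)
    cat("  flag: no strong cluster structure (all mean silhouettes < 0.4)\n")
})

#' Map cluster labels to (replica, time) frame ranges
#'
#' Compresses each cluster's frames into maximal contiguous runs of global
#' 0-based frame indices and summarizes the replica composition per cluster
#' (clusters in this kind of data tend to be dominated by one replica).
#'
#' @param model a [ClusterModel-class].
#' @param frames data.frame (replica_id, time_ns), one row per frame, or an
#'   object with a [frameLabels()] method.
#' @return List with `runs` (data.frame cluster, run_start, run_end,
#'   replica_id, time_start_ns, time_end_ns) and `replicaComposition`
#'   (data.frame cluster, replica_id, n_frames, fraction).
#' @export
mapClustersToFrames <- function(model, frames) {
  stopifnot(is(model, "ClusterModel"))
  fl <- if (is.data.frame(frames)) frames else frameLabels(frames)
  if (length(model@labels) == 0L) stop("precondition error: empty cluster model")
  stopifnot(nrow(fl) == length(model@labels))
  lab <- model@labels
  runs <- lapply(sort(unique(lab)), function(cl) {
    ix <- which(lab == cl) - 1L                 # 0-based global indices
    breaks <- c(0L, which(diff(ix) > 1L), length(ix))
    do.call(rbind, lapply(seq_len(length(breaks) - 1L), function(r) {
      seg <- ix[(breaks[r] + 1L):breaks[r + 1L]]
      data.frame(cluster = cl, run_start = seg[1], run_end = seg[length(seg)],
                 replica_id = fl$replica_id[seg[1] + 1L],
                 time_start_ns = fl$time_ns[seg[1] + 1L],
                 time_end_ns = fl$time_ns[seg[length(seg)] + 1L])
    }))
  })
  comp <- do.call(rbind, lapply(sort(unique(lab)), function(cl) {
    tab <- table(fl$replica_id[lab == cl])
    data.frame(cluster = cl, replica_id = as.integer(names(tab)),
               n_frames = as.integer(tab),
               fraction = as.numeric(tab) / sum(tab))
  }))
  list(runs = do.call(rbind, runs), replicaComposition = comp)
}

#' Select loadings by magnitude threshold
#'
#' A variable (residue, axis) is selected iff |loading| >= cutoff on at least
#' one considered component; the bound is inclusive, so a loading of exactly
#' the cutoff is selected.
#'
#' @param loadings matrix of loadings restricted to the considered components
#'   (variables x components), rows labelled by the coordinate-matrix column
#'   labels, or an [EssentialDynamicsResult-class] (its first `nPC` columns).
#' @param cutoff positive threshold (default 0.7).
#' @param nPC components considered when `loadings` is a PCA result (default 2).
#' @return A [LoadingSelection-class].
#' @export
selectLoadingsThreshold <- function(loadings, cutoff = 0.7, nPC = 2) {
  if (cutoff <= 0) stop("cutoff must be positive")
  lab <- NULL
  if (is(loadings, "EssentialDynamicsResult")) {
    lab <- loadings@columnLabels
    loadings <- loadings@loadings[, seq_len(min(nPC, ncol(loadings@loadings))),
                                  drop = FALSE]
  }
  loadings <- as.matrix(loadings)
  if (is.null(lab))
    lab <- data.frame(residue_index = seq_len(nrow(loadings)),
                      axis = rep(NA_character_, nrow(loadings)))
  sel <- which(apply(abs(loadings) >= cutoff, 1, any))
  vars <- cbind(lab[sel, , drop = FALSE],
                as.data.frame(loadings[sel, , drop = FALSE]),
                distance = sqrt(rowSums(loadings[sel, , drop = FALSE]^2)))
  rownames(vars) <- NULL
  new("LoadingSelection", method = "threshold", variables = vars,
      perCluster = list(), cutoff = cutoff)
}

#' Select the top fraction of loadings per loading-space cluster
#'
#' Loading points in the PC1/PC2 plane are themselves clustered by K-means
#' (with k taken from the score clustering, mirroring the per-cluster loading
#' analysis); within each cluster the variables are ranked by Euclidean
#' distance from the origin of the loading plane and the top `fraction` are
#' selected (at least ceiling(fraction * cluster size)); all ties at the
#' boundary distance are included and noted.
#'
#' @param loadings variables x 2 matrix of PC1/PC2 loading pairs, or an
#'   [EssentialDynamicsResult-class].
#' @param k number of loading-space clusters (typically the score-cluster
#'   count, e.g. `model@k`).
#' @param fraction fraction selected per cluster, in (0, 1] (default 0.10).
#' @param seed RNG seed for the K-means step.
#' @return A [LoadingSelection-class] with `perCluster` filled.
#' @export
selectLoadingsTopDecile <- function(loadings, k, fraction = 0.10, seed = 1) {
  if (fraction <= 0 || fraction > 1)
    stop("parameter error: fraction must lie in (0, 1]")
  lab <- NULL
  if (is(loadings, "EssentialDynamicsResult")) {
    lab <- loadings@columnLabels
    loadings <- loadings@loadings[, 1:2, drop = FALSE]
  }
  loadings <- as.matrix(loadings)
  if (nrow(loadings) < 10L) stop("need loadings for >= 10 variables")
  if (is.null(lab))
    lab <- data.frame(residue_index = seq_len(nrow(loadings)),
                      axis = rep(NA_character_, nrow(loadings)))
  km <- withr::with_seed(as.integer(seed),
    stats::kmeans(loadings, centers = k, nstart = 25, iter.max = 100))
  dist0 <- sqrt(rowSums(loadings^2))
  ties <- character(0)
  perCluster <- list()
  sel_all <- integer(0)
  for (cl in seq_len(k)) {
    ix <- which(km$cluster == cl)
    m <- ceiling(fraction * length(ix))
    d <- dist0[ix]
    boundary <- sort(d, decreasing = TRUE)[m]
    keep <- ix[d >= boundary]           # ties at the boundary all included
    if (length(keep) > m)
      ties <- c(ties, sprintf(
        "cluster %d: %d variables tied at boundary distance %g (all included)",
        cl - 1L, sum(d == boundary), boundary))
    vars <- cbind(lab[keep, , drop = FALSE],
                  as.data.frame(loadings[keep, , drop = FALSE]),
                  distance = dist0[keep],
                  cluster = cl - 1L)
    rownames(vars) <- NULL
    perCluster[[as.character(cl - 1L)]] <- vars[order(-vars$distance), ]
    sel_all <- c(sel_all, keep)
  }
  allvars <- do.call(rbind, perCluster)
  rownames(allvars) <- NULL
  new("LoadingSelection", method = "top_decile", variables = allvars,
      perCluster = perCluster, cutoff = fraction, tieNote = ties)
}

setMethod("show", "LoadingSelection", function(object) {
  cat("LoadingSelection (", object@method, "): ",
      nrow(object@variables), " variables selected",
      if (object@method == "threshold")
        sprintf(" at |loading| >= %g", object@cutoff)
      else sprintf(" (top %g%% per cluster, %d clusters)",
                   100 * object@cutoff, length(object@perCluster)),
      "\n", sep = "")
  for (note in object@tieNote) cat("  tie note:", note, "\n")
})
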