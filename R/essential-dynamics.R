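#' Principal component analysis of a coordinate matrix
#'
#' Eigendecomposition of the column covariance (the correlation matrix when
#' the input was passed through [standardizeColumns()], the classical
#' covariance-based essential dynamics otherwise), computed through the thin
#' SVD of the centered data. Loadings are unit-norm eigenvectors with a fixed
#' sign convention (the largest-magnitude entry of each column is positive, so
#' output is deterministic across eigensolvers); scores are the centered data
#' projected onto the loadings, hence the variance of score column c equals
#' eigenvalue c.
#'
#' @param m a [CoordinateMatrix-class] with >= 2 frames.
#' @return An [EssentialDynamicsResult-class] with `kRetained` initialized to
#'   the full component count; apply [retainComponents()] or
#'   [parallelAnalysis()] to restrict it.
#' @export
essentialDynamics <- function(m) {
  stopifnot(is(m, "CoordinateMatrix"))
  X <- m@values
  if (!all(is.finite(X))) stop("data error: non-finite entries in coordinate matrix")
  n <- nrow(X)
  if (n < 2L) stop("PCA needs >= 2 frames")
  Xc <- sweep(X, 2, colMeans(X))   # no-op when already standardized
  sv <- svd(Xc)
  k <- min(dim(X))
  ev <- (sv$d^2) / (n - 1)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d, nrow = k)
  ## sign convention: largest-|entry| of each loading positive
  flip <- vapply(seq_len(k), function(j) {
    e <- loadings[, j]
    sign(e[which.max(abs(e))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  rownames(loadings) <- colnames(X)
  vp <- if (sum(ev) > 0) ev / sum(ev) else rep(0, k)
  new("EssentialDynamicsResult",
      eigenvalues = ev, varianceProportion = vp,
      cumulativeProportion = cumsum(vp),
      scores = scores, loadings = loadings,
      kRetained = k, standardized = m@standardized,
      columnLabels = m@columnLabels, frameLabels = m@frameLabels)
}

setMethod("show", "EssentialDynamicsResult", function(object) {
  k <- min(3L, length(object@eigenvalues))
  cat("EssentialDynamicsResult:", nrow(object@scores), "frames,",
      nrow(object@loadings), "variables,",
      length(object@eigenvalues), "components\n")
  cat("  basis:", if (object@standardized) "correlation (standardized)" else
        "covariance", "| retained:", object@kRetained, "\n")
  cat("  leading eigenvalues:",
      paste(format(object@eigenvalues[seq_len(k)], digits = 4), collapse = ", "),
      "\n")
  cat("  cumulative variance (first", k, "):",
      sprintf("%.1f%%", 100 * object@cumulativeProportion[k]), "\n")
})

#' @describeIn essentialDynamics frame labels of the scores
#' @param x an EssentialDynamicsResult
#' @export
setMethod("frameLabels", "EssentialDynamicsResult", function(x) x@frameLabels)

#' Restrict the retained-component count of a PCA result
#' @param res an [EssentialDynamicsResult-class].
#' @param k number of components to retain (>= 1).
#' @return The result with `kRetained` set.
#' @export
retainComponents <- function(res, k) {
  stopifnot(is(res, "EssentialDynamicsResult"),
            k >= 1L, k <= length(res@eigenvalues))
  res@kRetained <- as.integer(k)
  res
}

## Leading eigenvalues of the column covariance/correlation, via thin SVD.
.cov_eigenvalues <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  svd(Xc, nu = 0, nv = 0)$d^2 / (nrow(X) - 1)
}

#' Horn's parallel analysis for component retention
#'
#' Compares the observed eigenvalue spectrum against the spectrum of noise
#' data. The default ("permutation") draws `nDraws` matrices by independently
#' permuting each column of the input, which preserves marginal distributions
#' while destroying inter-column correlation; the "normal" variant draws iid
#' standard-normal matrices of the same shape (appropriate for standardized
#' input). For each component the noise threshold is the conservative
#' order-statistic percentile `sort(noise)[ceiling((nDraws + 1) * percentile)]`
#' and components are retained while observed > threshold, stopping at the
#' first failure.
#'
#' @param m a standardized [CoordinateMatrix-class].
#' @param nDraws number of noise draws (default 100; < 10 warns).
#' @param percentile noise percentile in (0, 1), default 0.95.
#' @param seed RNG seed; results are reproducible under a fixed seed.
#' @param method "permutation" (default) or "normal".
#' @return A [ParallelAnalysisResult-class].
#' @export
parallelAnalysis <- function(m, nDraws = 100, percentile = 0.95, seed = 1,
                             method = c("permutation", "normal")) {
  method <- match.arg(method)
  stopifnot(is(m, "CoordinateMatrix"))
  if (!m@standardized)
    warning("parallel analysis is intended for standardized input")
  if (nDraws < 10) warning("nDraws < 10 gives unstable noise percentiles")
  X <- m@values
  obs <- .cov_eigenvalues(X)
  k <- length(obs)
  noise <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nDraws), function(d) {
      N <- if (method == "permutation") apply(X, 2, sample) else
        matrix(stats::rnorm(length(X)), nrow(X), ncol(X))
      ev <- .cov_eigenvalues(N)
      length(ev) <- k   # pad with NA if rank differs (it cannot here)
      ev
    }, numeric(k))
  })
  pos <- min(ceiling((nDraws + 1) * percentile), nDraws)
  thresholds <- apply(noise, 1, function(v) sort(v)[pos])
  exceed <- obs > thresholds
  kRet <- if (all(exceed)) k else which(!exceed)[1] - 1L
  new("ParallelAnalysisResult", observedEigenvalues = obs,
      noisePercentiles = thresholds, kRetained = as.integer(kRet),
      nDraws = as.integer(nDraws), percentile = percentile,
      seed = as.integer(seed), method = method)
}

setMethod("show", "ParallelAnalysisResult", function(object) {
  cat("ParallelAnalysisResult (", object@method, "):",
      object@kRetained, "components retained\n")
  k <- min(5L, length(object@observedEigenvalues))
  cat("  observed:",
      paste(format(object@observedEigenvalues[seq_len(k)], digits = 4),
            collapse = ", "), "...\n")
  cat("  noise ", object@percentile * 100, "th pct: ",
      paste(format(object@noisePercentiles[seq_len(k)], digits = 4),
            collapse = ", "), " ...\n", sep = "")
})

#' Scree table of a PCA spectrum
#'
#' First `nShow` rows of the spectrum in the summary-table layout:
#' component, eigenvalue, proportion of variance (%), cumulative proportion of
#' variance (%).
#'
#' @param res an [EssentialDynamicsResult-class].
#' @param nShow rows to show (truncated at the spectrum length).
#' @return data.frame (component, eigenvalue, proportion_pct, cumulative_pct).
#' @export
screeData <- function(res, nShow = 10) {
  stopifnot(is(res, "EssentialDynamicsResult"))
  n <- min(nShow, length(res@eigenvalues))
  data.frame(component = paste0("PC", seq_len(n)),
             eigenvalue = res@eigenvalues[seq_len(n)],
             proportion_pct = 100 * res@varianceProportion[seq_len(n)],
             cumulative_pct = 100 * res@cumulativeProportion[seq_len(n)])
}

#' Summary table in the style of a principal-components summary
#'
#' One row per structure/run: eigenvalue and cumulative proportion of variance
#' (%) for the first `nPC` components.
#'
#' @param res an [EssentialDynamicsResult-class].
#' @param nPC components to report (default 3).
#' @param label row label.
#' @return One-row data.frame with columns PC<i>_eigenvalue,
#'   PC<i>_cumulative_pct.
#' @export
pcaSummaryTable <- function(res, nPC = 3, label = "run") {
  nPC <- min(nPC, length(res@eigenvalues))
  out <- data.frame(structure = label)
  for (i in seq_len(nPC)) {
    out[[paste0("PC", i, "_eigenvalue")]] <- res@eigenvalues[i]
    out[[paste0("PC", i, "_cumulative_pct")]] <- 100 * res@cumulativeProportion[i]
  }
  out
}
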