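#' Kabsch least-squares superposition of two point sets
#'
#' Finds the proper rotation R and translation t minimizing the RMSD between
#' `mobile` (after transform) and `reference`, via SVD of the cross-covariance
#' with determinant correction so that det(R) = +1 (no reflections). The
#' transform maps a mobile point x to \code{R \%*\% (x - centroid_mobile) +
#' centroid_reference}, i.e. `rotation` and `translation` satisfy
#' \code{x_fit = x R^T + t} in row-vector convention.
#'
#' @param mobile,reference N x 3 matrices of paired Calpha positions, N >= 3.
#' @return A list of class `SuperpositionResult`: `rotation` (3 x 3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom, after transform).
#' @export
kabschFit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("mobile and reference must have equal point counts")
  if (nrow(mobile) < 3L)
    stop("insufficient points: Kabsch superposition needs >= 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  ## degenerate (collinear) sets: rank of A or B < 2
  if (min(svd(A)$d[2], svd(B)$d[2]) < 1e-10 * max(1, max(abs(A)), max(abs(B))))
    warning("degenerate (collinear) point set; superposition is a best-effort fit")
  H <- crossprod(A, B)               # 3 x 3 cross-covariance
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cr - R %*% cm)
  fitted <- tcrossprod(mobile, R) + matrix(t_vec, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat("SuperpositionResult: rmsd =", format(x$rmsd, digits = 6), "Angstrom\n")
  invisible(x)
}

#' Apply a SuperpositionResult to a point set
#' @param fit a result of [kabschFit()].
#' @param coords N x 3 matrix.
#' @return Transformed N x 3 matrix.
#' @export
applySuperposition <- function(fit, coords) {
  tcrossprod(as.matrix(coords), fit$rotation) +
    matrix(fit$translation, nrow(coords), 3, byrow = TRUE)
}

#' Superpose every frame of a trajectory onto a reference
#'
#' Each frame is independently Kabsch-fit (Calpha, all residues by default) to
#' the reference frame; the result carries an alignment provenance flag and the
#' reference label. By default the reference is the first frame of the first
#' replica.
#'
#' @param traj a [Trajectory-class].
#' @param reference a [Frame-class] sharing the residue set (default: frame 1).
#' @param mask optional logical or integer residue selector used for the fit
#'   (all residues are still transformed).
#' @return The aligned [Trajectory-class].
#' @export
superposeTrajectory <- function(traj, reference = getFrame(traj, 1), mask = NULL) {
  stopifnot(is(traj, "Trajectory"), is(reference, "Frame"))
  if (!identical(residueIndex(reference), residueIndex(traj)))
    stop("reference must share the trajectory's residue set")
  sel <- if (is.null(mask)) seq_len(nResidues(traj)) else mask
  out <- traj@coords
  for (f in seq_len(nFrames(traj))) {
    frame_xyz <- traj@coords[f, , , drop = TRUE]
    fit <- tryCatch(
      kabschFit(frame_xyz[sel, , drop = FALSE],
                reference@coords[sel, , drop = FALSE]),
      error = function(e) stop("frame ", f - 1L, ": ", conditionMessage(e))
    )
    out[f, , ] <- applySuperposition(fit, frame_xyz)
  }
  Trajectory(out, residueIndex = traj@residueIndex,
             residueName = traj@residueName, element = traj@element,
             replicaId = traj@replicaId, timeNs = traj@timeNs,
             snapshotIntervalNs = traj@snapshotIntervalNs,
             aligned = TRUE,
             referenceLabel = sprintf("replica %d @ %g ns",
                                      reference@replicaId, reference@timeNs))
}

#' Per-frame Calpha RMSD of a trajectory to a reference frame
#' @param traj a [Trajectory-class].
#' @param reference a [Frame-class].
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsdToReference <- function(traj, reference) {
  vapply(seq_len(nFrames(traj)), function(f) {
    sqrt(mean(rowSums((traj@coords[f, , , drop = TRUE] - reference@coords)^2)))
  }, numeric(1))
}
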