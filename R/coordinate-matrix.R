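#' Build the frames x 3N coordinate matrix from an aligned trajectory
#'
#' Columns are ordered x, y, z per residue with residues ascending, so a
#' 449-residue chain yields 1347 columns; row r reshaped to N x 3 recovers
#' frame r's Calpha coordinates exactly. Building from an unaligned trajectory
#' raises a warning (not an error): rigid-body motion then leaks into the
#' covariance.
#'
#' @param traj a [Trajectory-class], normally after [superposeTrajectory()].
#' @return A [CoordinateMatrix-class].
#' @export
buildCoordinateMatrix <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  if (!isAligned(traj))
    warning("trajectory carries no alignment provenance; ",
            "superpose it before PCA unless rigid motion is intended")
  nf <- nFrames(traj); nr <- nResidues(traj)
  ## interleave axes: columns r1_x, r1_y, r1_z, r2_x, ...
  m <- matrix(aperm(traj@coords, c(1, 3, 2)), nrow = nf, ncol = 3L * nr)
  cl <- data.frame(residue_index = rep(traj@residueIndex, each = 3L),
                   axis = rep(c("x", "y", "z"), nr))
  colnames(m) <- paste0("r", cl$residue_index, "_", cl$axis)
  new("CoordinateMatrix", values = m, columnLabels = cl,
      frameLabels = frameLabels(traj), standardized = FALSE,
      aligned = isAligned(traj))
}

#' @describeIn buildCoordinateMatrix number of frames (rows)
#' @param x a CoordinateMatrix
#' @export
setMethod("nFrames", "CoordinateMatrix", function(x) nrow(x@values))

#' @describeIn buildCoordinateMatrix number of residues (columns / 3)
#' @export
setMethod("nResidues", "CoordinateMatrix", function(x) ncol(x@values) %/% 3L)

#' @describeIn buildCoordinateMatrix frame (replica, time) labels
#' @export
setMethod("frameLabels", "CoordinateMatrix", function(x) x@frameLabels)

#' @describeIn buildCoordinateMatrix alignment provenance
#' @export
setMethod("isAligned", "CoordinateMatrix", function(x) x@aligned)

setMethod("show", "CoordinateMatrix", function(object) {
  cat("CoordinateMatrix:", nrow(object@values), "frames x",
      ncol(object@values), "columns (", nResidues(object), "residues )\n")
  cat("  standardized:", object@standardized,
      "| aligned:", object@aligned, "\n")
  if (length(object@zeroVariance))
    cat("  zero-variance columns:", length(object@zeroVariance), "\n")
})

#' Column-standardize a coordinate matrix
#'
#' Centers every column to mean 0 and scales to sample sd 1 (the standard
#' preprocessing before correlation-matrix PCA). Zero-variance columns are left
#' at 0 and flagged in the `zeroVariance` slot. Per-column means and sds are
#' stored so the operation is invertible.
#'
#' @param m a [CoordinateMatrix-class] with >= 2 frames.
#' @return The standardized [CoordinateMatrix-class].
#' @export
standardizeColumns <- function(m) {
  stopifnot(is(m, "CoordinateMatrix"))
  if (nrow(m@values) < 2L) stop("standardization needs >= 2 frames")
  mu <- colMeans(m@values)
  sdv <- apply(m@values, 2, stats::sd)
  zero <- which(sdv == 0)
  scl <- ifelse(sdv == 0, 1, sdv)
  v <- sweep(sweep(m@values, 2, mu), 2, scl, "/")
  v[, zero] <- 0
  new("CoordinateMatrix", values = v, columnLabels = m@columnLabels,
      frameLabels = m@frameLabels, standardized = TRUE,
      centers = mu, scales = scl, zeroVariance = as.integer(zero),
      aligned = m@aligned)
}

#' Write / read the CSV coordinate-matrix dialect
#'
#' Header row of labels `r{index}_{x|y|z}`, one row per frame, first two
#' columns `replica_id` and `time_ns`.
#'
#' @param m a [CoordinateMatrix-class].
#' @param path CSV file path.
#' @return `writeCoordinateMatrixCSV` invisibly returns `path`;
#'   `readCoordinateMatrixCSV` returns a [CoordinateMatrix-class].
#' @export
writeCoordinateMatrixCSV <- function(m, path) {
  stopifnot(is(m, "CoordinateMatrix"))
  df <- cbind(m@frameLabels, as.data.frame(m@values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCoordinateMatrixCSV
#' @export
readCoordinateMatrixCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("replica_id", "time_ns") %in% names(df)))
  vals <- as.matrix(df[, setdiff(names(df), c("replica_id", "time_ns")), drop = FALSE])
  lab <- colnames(vals)
  parts <- regmatches(lab, regexec("^r([0-9]+)_([xyz])$", lab))
  if (any(lengths(parts) != 3L)) stop("malformed coordinate column labels")
  cl <- data.frame(residue_index = as.integer(vapply(parts, `[`, "", 2)),
                   axis = vapply(parts, `[`, "", 3))
  new("CoordinateMatrix", values = vals, columnLabels = cl,
      frameLabels = df[, c("replica_id", "time_ns")], standardized = FALSE,
      aligned = TRUE)
}
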