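## Van der Waals radii (Angstrom) for the Shrake-Rupley lattice and atomic
## masses (u) for mass-weighted Rg. Radii: Bondi-style values commonly used for
## protein SASA.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.atomic_mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008, P = 30.974)

#' Root-mean-square fluctuation per residue
#'
#' RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2) on an aligned trajectory. Two
#' scopes are provided because how the source data's per-replica fluctuations
#' were merged is ambiguous: `"per-replica-combined"` (default) computes each
#' replica's RMSF about that replica's own mean and combines them as the root
#' of the frame-weighted mean of squares; `"whole-concatenation"` uses the
#' global per-residue mean across all frames.
#'
#' @param traj an aligned [Trajectory-class] with >= 2 frames.
#' @param scope "per-replica-combined" or "whole-concatenation".
#' @return data.frame (residue_index, rmsf) in Angstrom.
#' @export
rmsf <- function(traj, scope = c("per-replica-combined", "whole-concatenation")) {
  scope <- match.arg(scope)
  stopifnot(is(traj, "Trajectory"))
  if (nFrames(traj) < 2L)
    stop("undefined variance: RMSF needs >= 2 frames")
  msf_about_own_mean <- function(ix) {
    ## mean squared fluctuation per residue over frames ix
    sub <- traj@coords[ix, , , drop = FALSE]
    mu <- apply(sub, c(2, 3), mean)
    dev <- sweep(sub, c(2, 3), mu)
    apply(dev^2, 2, sum) / length(ix)   # sums over frames and axes
  }
  if (scope == "whole-concatenation") {
    msf <- msf_about_own_mean(seq_len(nFrames(traj)))
  } else {
    groups <- split(seq_len(nFrames(traj)), traj@replicaId)
    per <- vapply(groups, msf_about_own_mean, numeric(nResidues(traj)))
    w <- vapply(groups, length, integer(1))
    msf <- as.numeric(per %*% w) / sum(w)
  }
  data.frame(residue_index = traj@residueIndex, rmsf = sqrt(msf))
}

#' Radius of gyration of a frame
#'
#' Rg = sqrt(sum_k w_k |r_k - r_cm|^2 / sum_k w_k). Weighting is uniform by
#' default (appropriate for Calpha-only traces); `"mass"` uses atomic masses
#' from the element annotation.
#'
#' @param frame a [Frame-class].
#' @param weighting "uniform" or "mass".
#' @return Rg in Angstrom.
#' @export
radiusOfGyration <- function(frame, weighting = c("uniform", "mass")) {
  weighting <- match.arg(weighting)
  stopifnot(is(frame, "Frame"), nrow(frame@coords) >= 1L)
  w <- if (weighting == "uniform") rep(1, nrow(frame@coords)) else {
    m <- .atomic_mass[frame@element]
    if (anyNA(m)) stop("unknown element for mass weighting: ",
                       paste(unique(frame@element[is.na(m)]), collapse = ", "))
    as.numeric(m)
  }
  cm <- colSums(frame@coords * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(frame@coords, 2, cm)^2)) / sum(w))
}

#' Per-frame radius of gyration series for a trajectory
#' @param traj a [Trajectory-class].
#' @param weighting passed to [radiusOfGyration()].
#' @return data.frame (replica_id, time_ns, rg).
#' @export
radiusOfGyrationSeries <- function(traj, weighting = "uniform") {
  vals <- vapply(seq_len(nFrames(traj)), function(f)
    radiusOfGyration(getFrame(traj, f), weighting), numeric(1))
  cbind(frameLabels(traj), rg = vals)
}

## Fibonacci sphere lattice: n nearly-uniform points on the unit sphere.
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)   # golden-angle increments
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the atomic van der Waals spheres: each atom's
#' expanded sphere (r_atom + probe) is sampled on a Fibonacci lattice, and its
#' accessible area is the exposed-point fraction times 4 pi (r_atom + probe)^2.
#' Element radii come from a built-in table (C 1.7, N 1.55, O 1.52, S 1.8,
#' H 1.2 Angstrom).
#'
#' @param frame a [Frame-class].
#' @param probeRadius probe radius, Angstrom (water: 1.4).
#' @param nSpherePoints lattice points per atom (default 960).
#' @return List with `perAtom` (data.frame residue_index, area) and `total`
#'   (Angstrom^2).
#' @export
sasaShrakeRupley <- function(frame, probeRadius = 1.4, nSpherePoints = 960) {
  stopifnot(is(frame, "Frame"))
  rad <- .vdw_radii[frame@element]
  if (anyNA(rad))
    stop("unknown element in radius lookup: ",
         paste(unique(frame@element[is.na(rad)]), collapse = ", "))
  rad <- as.numeric(rad) + probeRadius
  n <- nrow(frame@coords)
  sphere <- .fibonacci_sphere(nSpherePoints)
  d2 <- as.matrix(stats::dist(frame@coords))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    pts <- sphere * rad[i] +
      matrix(frame@coords[i, ], nSpherePoints, 3, byrow = TRUE)
    exposed <- rep(TRUE, nSpherePoints)
    for (j in nb) {
      dj <- (pts[, 1] - frame@coords[j, 1])^2 +
            (pts[, 2] - frame@coords[j, 2])^2 +
            (pts[, 3] - frame@coords[j, 3])^2
      exposed <- exposed & dj >= rad[j]^2
      if (!any(exposed)) break
    }
    area[i] <- sum(exposed) / nSpherePoints * 4 * pi * rad[i]^2
  }
  list(perAtom = data.frame(residue_index = frame@residueIndex, area = area),
       total = sum(area))
}

#' Per-frame total SASA series for a trajectory
#' @param traj a [Trajectory-class].
#' @param ... passed to [sasaShrakeRupley()].
#' @return data.frame (replica_id, time_ns, sasa).
#' @export
sasaSeries <- function(traj, ...) {
  vals <- vapply(seq_len(nFrames(traj)), function(f)
    sasaShrakeRupley(getFrame(traj, f), ...)$total, numeric(1))
  cbind(frameLabels(traj), sasa = vals)
}

#' Descriptive statistics of a per-frame series
#'
#' Mean, sd (sample by default), min, max and per-replica means, matching the
#' layout of the descriptive-statistics tables this pipeline reports.
#'
#' @param values numeric vector, one value per frame.
#' @param replicaId optional per-frame replica labels for per-replica means.
#' @param sdType "sample" (n - 1) or "population" (n).
#' @return List (mean, sd, min, max, perReplicaMeans, perReplicaSds).
#' @export
seriesStats <- function(values, replicaId = NULL, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  stopifnot(length(values) >= 1L)
  n <- length(values)
  s <- if (n == 1L) 0 else stats::sd(values)
  if (sdType == "population") s <- s * sqrt((n - 1) / n)
  per_mean <- per_sd <- numeric(0)
  if (!is.null(replicaId)) {
    groups <- split(values, replicaId)
    per_mean <- vapply(groups, mean, numeric(1))
    per_sd <- vapply(groups, function(v) if (length(v) == 1L) 0 else stats::sd(v),
                     numeric(1))
  }
  list(mean = mean(values), sd = s, min = min(values), max = max(values),
       perReplicaMeans = per_mean, perReplicaSds = per_sd)
}

#' Stamp a per-residue profile into the B-factor column of a PDB file
#'
#' Writes the first frame of `traj` as a single-model PDB whose B-factor
#' column holds `profile$value` (e.g. RMSF) for coloring in molecular viewers.
#'
#' @param traj a [Trajectory-class].
#' @param profile data.frame (residue_index, value-like second column).
#' @param path output PDB path.
#' @return Invisibly, `path`.
#' @export
writeBFactorPDB <- function(traj, profile, path) {
  stopifnot(is(traj, "Trajectory"), nrow(profile) == nResidues(traj))
  vals <- profile[[2]]
  xyz <- traj@coords[1, , , drop = TRUE]
  lines <- sprintf(
    "ATOM  %5d  CA  %-3s A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           %-2s",
    seq_len(nResidues(traj)), traj@residueName, traj@residueIndex,
    xyz[, 1], xyz[, 2], xyz[, 3], pmin(vals, 999.99), traj@element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
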