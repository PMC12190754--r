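#' Attach a per-frame energy series to trajectory frame labels
#'
#' Matches an energy table to the trajectory's (replica_id, time_ns) labels,
#' reordering rows as needed. Missing or extra rows are reported by frame.
#'
#' @param frames data.frame (replica_id, time_ns) or an object with a
#'   [frameLabels()] method.
#' @param energies data.frame with columns replica_id, time_ns,
#'   dG_kJ_per_mol, or a CSV path to one.
#' @return An [EnergySeries-class] aligned to the frame order.
#' @export
attachEnergy <- function(frames, energies) {
  fl <- if (is.data.frame(frames)) frames else frameLabels(frames)
  if (is.character(energies)) energies <- utils::read.csv(energies)
  stopifnot(all(c("replica_id", "time_ns", "dG_kJ_per_mol") %in% names(energies)))
  key <- function(df) paste(df$replica_id, df$time_ns, sep = "@")
  kf <- key(fl); ke <- key(energies)
  missing <- setdiff(kf, ke); extra <- setdiff(ke, kf)
  if (length(missing) || length(extra)) {
    stop("alignment error: ",
         if (length(missing)) paste0("missing frames: ",
           paste0("(replica ", sub("@", ", time ", missing), " ns)",
                  collapse = ", ")) else "",
         if (length(missing) && length(extra)) "; " else "",
         if (length(extra)) paste0("extra frames: ",
           paste0("(replica ", sub("@", ", time ", extra), " ns)",
                  collapse = ", ")) else "")
  }
  if (anyDuplicated(ke)) stop("alignment error: duplicated frame labels in energies")
  new("EnergySeries", frameLabels = fl,
      dG = energies$dG_kJ_per_mol[match(kf, ke)])
}

setMethod("show", "EnergySeries", function(object) {
  cat("EnergySeries:", length(object@dG), "frames, dG in kJ/mol\n")
  cat("  range:", format(min(object@dG), digits = 5), "..",
      format(max(object@dG), digits = 5), "\n")
})

#' @describeIn attachEnergy frame labels of an EnergySeries
#' @param x an EnergySeries
#' @export
setMethod("frameLabels", "EnergySeries", function(x) x@frameLabels)

#' Free-energy landscape over the PC1/PC2 plane
#'
#' Piecewise-linear interpolation of the per-frame dG values over the Delaunay
#' triangulation of the (PC1, PC2) score points onto a regular grid
#' ([interp::interp()]). Grid nodes outside the convex hull of the scores are
#' NA (undefined); at the data points the interpolant reproduces the input
#' values exactly. Duplicated score points are averaged before triangulation.
#'
#' @param scores n x 2 matrix (or more columns; the first two are used) of PC
#'   scores, or an [EssentialDynamicsResult-class].
#' @param energy an [EnergySeries-class] (or numeric vector) with one value
#'   per frame.
#' @param gridN grid resolution per axis (default 100).
#' @return A [FreeEnergyLandscape-class].
#' @export
buildLandscape <- function(scores, energy, gridN = 100) {
  if (is(scores, "EssentialDynamicsResult")) scores <- scores@scores
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  dG <- if (is(energy, "EnergySeries")) energy@dG else as.numeric(energy)
  stopifnot(nrow(scores) == length(dG))
  if (nrow(scores) < 3L) stop("need >= 3 score points")
  ## collinearity check: rank of centered scores
  sv <- svd(sweep(scores, 2, colMeans(scores)), nu = 0, nv = 0)$d
  if (sv[2] < 1e-10 * max(sv[1], 1))
    stop("degeneracy error: score points are collinear")
  res <- interp::interp(scores[, 1], scores[, 2], dG,
                        nx = gridN, ny = gridN,
                        method = "linear", duplicate = "mean")
  pts <- data.frame(pc1 = scores[, 1], pc2 = scores[, 2], dG = dG)
  new("FreeEnergyLandscape", gridPC1 = res$x, gridPC2 = res$y,
      dGGrid = res$z, stats = list(), points = pts)
}

setMethod("show", "FreeEnergyLandscape", function(object) {
  def <- !is.na(object@dGGrid)
  cat("FreeEnergyLandscape:", length(object@gridPC1), "x",
      length(object@gridPC2), "grid,", sum(def), "nodes defined\n")
  if (any(def))
    cat("  dG range:", format(min(object@dGGrid[def]), digits = 5), "..",
        format(max(object@dGGrid[def]), digits = 5), "kJ/mol\n")
})

#' Evaluate a landscape's interpolant at arbitrary points
#' @param landscape a [FreeEnergyLandscape-class].
#' @param pc1,pc2 coordinates.
#' @return Interpolated dG values (NA outside the data hull).
#' @export
landscapeAt <- function(landscape, pc1, pc2) {
  interp::interp(landscape@points$pc1, landscape@points$pc2,
                 landscape@points$dG, output = "points",
                 xo = pc1, yo = pc2, method = "linear",
                 duplicate = "mean")$z
}

#' Local minima of a gridded landscape, filtered by topographic persistence
#'
#' Raw 8-neighbour grid minima of a piecewise-linear interpolant include tiny
#' triangulation dips along ridges, so minima are extracted by 0-dimensional
#' persistence (watershed flooding): defined nodes are processed in ascending
#' dG order, each new connected component records a candidate minimum, and
#' when two components meet at a saddle the shallower one dies with
#' persistence = saddle dG - its minimum dG. Only minima whose persistence is
#' at least `minProminence` (default: 1% of the defined dG range) survive; the
#' deepest basin always does.
#'
#' @param landscape a [FreeEnergyLandscape-class].
#' @param minProminence minimum basin depth below its escape saddle, kJ/mol;
#'   NULL for the 1%-of-range default.
#' @return data.frame (pc1, pc2, dG, prominence), deepest first.
#' @export
landscapeMinima <- function(landscape, minProminence = NULL) {
  z <- landscape@dGGrid
  nx <- nrow(z); ny <- ncol(z)
  def <- which(!is.na(z))
  empty <- data.frame(pc1 = numeric(0), pc2 = numeric(0), dG = numeric(0),
                      prominence = numeric(0))
  if (length(def) == 0L) return(empty)
  if (is.null(minProminence))
    minProminence <- 0.01 * diff(range(z[def]))
  ord <- def[order(z[def])]
  ## union-find over basin ids
  parent <- integer(0); bmin <- numeric(0); bnode <- integer(0); pers <- numeric(0)
  find <- function(b) { while (parent[b] != b) b <- parent[b]; b }
  basin_of <- integer(nx * ny)         # 0 = unprocessed
  for (node in ord) {
    i <- (node - 1L) %% nx + 1L; j <- (node - 1L) %/% nx + 1L
    nbs <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- i + di; jj <- j + dj
      if (ii < 1L || ii > nx || jj < 1L || jj > ny) next
      b <- basin_of[(jj - 1L) * nx + ii]
      if (b > 0L) nbs <- c(nbs, find(b))
    }
    nbs <- unique(nbs)
    if (length(nbs) == 0L) {
      parent <- c(parent, length(parent) + 1L)
      bmin <- c(bmin, z[node]); bnode <- c(bnode, node)
      pers <- c(pers, NA_real_)        # still alive
      basin_of[node] <- length(parent)
    } else {
      target <- nbs[which.min(bmin[nbs])]
      for (b in setdiff(nbs, target)) {
        pers[b] <- z[node] - bmin[b]   # shallower basin dies at this saddle
        parent[b] <- target
      }
      basin_of[node] <- target
    }
  }
  alive <- which(parent == seq_along(parent))
  pers[alive] <- Inf
  keep <- which(pers >= minProminence)
  if (length(keep) == 0L) return(empty)
  i <- (bnode[keep] - 1L) %% nx + 1L; j <- (bnode[keep] - 1L) %/% nx + 1L
  res <- data.frame(pc1 = landscape@gridPC1[i], pc2 = landscape@gridPC2[j],
                    dG = z[bnode[keep]], prominence = pers[keep])
  res[order(res$dG), ]
}

#' Descriptive free-energy statistics in the summary-table layout
#'
#' Overall mean (with sd), minimum, maximum, and per-replica means (with sds);
#' per-cluster means are added when a [ClusterModel-class] is supplied.
#'
#' @param energy an [EnergySeries-class].
#' @param clusters optional [ClusterModel-class] over the same frames.
#' @param label row label.
#' @return One-row data.frame: structure, average, sd, minimum, maximum,
#'   trajectory<r>_average (and cluster<c>_average), kJ/mol.
#' @export
landscapeStats <- function(energy, clusters = NULL, label = "run") {
  stopifnot(is(energy, "EnergySeries"))
  st <- seriesStats(energy@dG, replicaId = energy@frameLabels$replica_id)
  out <- data.frame(structure = label, average = st$mean, sd = st$sd,
                    minimum = st$min, maximum = st$max)
  for (r in seq_along(st$perReplicaMeans)) {
    out[[paste0("trajectory", names(st$perReplicaMeans)[r], "_average")]] <-
      st$perReplicaMeans[[r]]
    out[[paste0("trajectory", names(st$perReplicaMeans)[r], "_sd")]] <-
      st$perReplicaSds[[r]]
  }
  if (!is.null(clusters)) {
    stopifnot(length(clusters@labels) == length(energy@dG))
    cm <- vapply(split(energy@dG, clusters@labels), mean, numeric(1))
    for (cl in names(cm)) out[[paste0("cluster", cl, "_average")]] <- cm[[cl]]
  }
  out
}

#' Pooled two-proportion Z-test
#'
#' z = (p2 - p1) / sqrt(phat (1 - phat) (1/n1 + 1/n2)) with the pooled
#' proportion phat = (s1 + s2)/(n1 + n2); two-sided normal p-value, no
#' continuity correction. Used to compare tunnel-presence frequencies between
#' two structure groups.
#'
#' @param s1,n1 successes and trials in group 1.
#' @param s2,n2 successes and trials in group 2.
#' @return A [ProportionTest-class].
#' @export
twoProportionZTest <- function(s1, n1, s2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, s1 >= 0, s2 >= 0, s1 <= n1, s2 <= n2)
  pooled <- (s1 + s2) / (n1 + n2)
  if (pooled == 0 || pooled == 1)
    stop("degenerate test: pooled proportion is ", pooled)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (s2 / n2 - s1 / n1) / se
  new("ProportionTest",
      successes1 = as.integer(s1), n1 = as.integer(n1),
      successes2 = as.integer(s2), n2 = as.integer(n2),
      p1 = s1 / n1, p2 = s2 / n2, pooled = pooled, se = se, z = z,
      pTwoSided = 2 * (1 - stats::pnorm(abs(z))))
}

setMethod("show", "ProportionTest", function(object) {
  cat("Two-proportion Z-test\n")
  cat(sprintf("  group 1: %d/%d (%.2f)  group 2: %d/%d (%.2f)\n",
              object@successes1, object@n1, object@p1,
              object@successes2, object@n2, object@p2))
  cat(sprintf("  pooled %.2f  se %.4f  z %.3f  p (two-sided) %.4f\n",
              object@pooled, object@se, object@z, object@pTwoSided))
})

#' Aggregate a tunnel-presence table to group counts and test them
#'
#' The table has one row per sampled frame with columns `group` and `present`
#' (0/1). Counts are aggregated per group (first group = group 1) and passed
#' to [twoProportionZTest()].
#'
#' @param tunnelTable data.frame (frame, group, present) or CSV path.
#' @return A [ProportionTest-class].
#' @export
tunnelPresenceTest <- function(tunnelTable) {
  if (is.character(tunnelTable)) tunnelTable <- utils::read.csv(tunnelTable)
  stopifnot(all(c("group", "present") %in% names(tunnelTable)))
  groups <- unique(tunnelTable$group)
  if (length(groups) != 2L) stop("tunnel table must contain exactly two groups")
  g1 <- tunnelTable$present[tunnelTable$group == groups[1]]
  g2 <- tunnelTable$present[tunnelTable$group == groups[2]]
  twoProportionZTest(sum(g1), length(g1), sum(g2), length(g2))
}

#' Contour plot of a free-energy landscape
#' @param landscape a [FreeEnergyLandscape-class].
#' @param ... passed to [graphics::filled.contour()].
#' @export
plotLandscape <- function(landscape, ...) {
  graphics::filled.contour(landscape@gridPC1, landscape@gridPC2,
                           landscape@dGGrid,
                           color.palette = grDevices::terrain.colors,
                           xlab = "PC1", ylab = "PC2",
                           main = "Free-energy landscape (kJ/mol)", ...)
  invisible(landscape)
}
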