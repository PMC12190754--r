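#' Specification of the synthetic trajectory world
#'
#' Constructs a [SyntheticSpec-class] whose defaults emulate the data regime
#' this pipeline targets: a 449-residue Calpha chain sampled as 3 replicas of
#' 101 snapshots (0-100 ns every 1 ns, 303 frames total), three dominant
#' collective modes with amplitude variances 9, 4, 1 Angstrom^2, one
#' conformational basin per replica (so clusters associate with replicas),
#' block-correlated motion planted on mode 1, random rigid-body nuisance
#' motion, an energy surface with minima at the basin centers, and a
#' tunnel-presence table with group probabilities 23/60 vs 38/60 sampled every
#' 5 ns (60 frames per group).
#'
#' @param nResidues chain length (default 449).
#' @param nReplicas replicas (default 3).
#' @param framesPerReplica snapshots per replica (default 101).
#' @param modeVariances descending per-mode amplitude variances, Angstrom^2.
#' @param modeBlocks list (one entry per mode, NULL allowed) of data.frames
#'   (from, to, sign) planting signed residue-block displacements.
#' @param basinMeans nReplicas x nModes matrix of per-replica amplitude means;
#'   the default places the replicas at 120-degree spacing, radius 15, in the
#'   (mode 1, mode 2) amplitude plane.
#' @param noiseSd isotropic per-atom positional noise sd, Angstrom (default 0.3).
#' @param rigidNuisance apply a random rigid rotation/translation per frame
#'   (default TRUE); superposition must remove it.
#' @param energyBaseline,energyDepths,energyWeights,energyNoiseSd energy model
#'   dG(t) = baseline + depth[replica] + sum_k w_k (a_k - mean_k)^2 + noise,
#'   kJ/mol.
#' @param tunnelProbs tunnel-presence probability per group (default
#'   c(23, 38)/60, the emulated counts).
#' @param tunnelEveryNs tunnel sampling stride, ns (default 5).
#' @param seed RNG seed.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nResidues = 449, nReplicas = 3, framesPerReplica = 101,
                          modeVariances = c(9, 4, 1),
                          modeBlocks = NULL,
                          basinMeans = NULL,
                          noiseSd = 0.3,
                          rigidNuisance = TRUE,
                          energyBaseline = 95,
                          energyDepths = NULL,
                          energyWeights = NULL,
                          energyNoiseSd = 3,
                          tunnelProbs = c(23, 38) / 60,
                          tunnelEveryNs = 5,
                          seed = 1) {
  nModes <- length(modeVariances)
  if (is.null(basinMeans)) {
    ang <- 2 * pi * (seq_len(nReplicas) - 1) / nReplicas + pi / 2
    basinMeans <- matrix(0, nReplicas, nModes)
    basinMeans[, 1] <- 15 * cos(ang)
    if (nModes >= 2) basinMeans[, 2] <- 15 * sin(ang)
  }
  if (is.null(modeBlocks)) {
    ## plant anti-correlated halves of the chain on mode 1
    half <- nResidues %/% 2L
    modeBlocks <- c(list(data.frame(from = c(1L, half + 1L),
                                    to = c(half, nResidues),
                                    sign = c(1, -1))),
                    rep(list(NULL), nModes - 1L))
  }
  if (is.null(energyDepths))
    energyDepths <- seq(0, by = 8, length.out = nReplicas)
  if (is.null(energyWeights))
    energyWeights <- c(0.08, 0.08, rep(0, max(0, nModes - 2L)))[seq_len(nModes)]
  new("SyntheticSpec",
      nResidues = as.integer(nResidues), nReplicas = as.integer(nReplicas),
      framesPerReplica = as.integer(framesPerReplica),
      modeVariances = modeVariances, modeBlocks = modeBlocks,
      basinMeans = basinMeans, noiseSd = noiseSd,
      rigidNuisance = rigidNuisance,
      energyBaseline = energyBaseline, energyDepths = energyDepths,
      energyWeights = energyWeights, energyNoiseSd = energyNoiseSd,
      tunnelProbs = tunnelProbs, tunnelEveryNs = tunnelEveryNs,
      seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@nResidues, "residues,", object@nReplicas,
      "replicas x", object@framesPerReplica, "frames\n")
  cat("  mode variances:", paste(object@modeVariances, collapse = ", "),
      "| noise sd:", object@noiseSd, "A | rigid nuisance:",
      object@rigidNuisance, "\n")
})

#' Reference Calpha chain: an ideal helix with 3.8 Angstrom spacing
#'
#' Builds a self-avoiding helical Calpha trace with exactly 3.8 Angstrom
#' consecutive spacing (helix radius 2.3 Angstrom, 100 degrees per residue,
#' rise chosen to close the 3.8 Angstrom constraint), centered at the origin
#' and placed in a seeded random orientation.
#'
#' @param nResidues chain length (>= 3).
#' @param seed RNG seed (orientation only; same seed, same chain).
#' @return A [Frame-class].
#' @export
makeReferenceChain <- function(nResidues, seed = 1) {
  stopifnot(nResidues >= 3)
  r <- 2.3
  theta <- 100 * pi / 180
  chord <- 2 * r * sin(theta / 2)
  rise <- sqrt(3.8^2 - chord^2)
  i <- seq_len(nResidues) - 1
  xyz <- cbind(r * cos(i * theta), r * sin(i * theta), rise * i)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  R <- withr::with_seed(as.integer(seed), .random_rotation())
  Frame(xyz %*% t(R), residueIndex = seq_len(nResidues))
}

## Haar-ish random proper rotation via QR of a Gaussian matrix.
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Orthonormal collective-mode displacement fields
#'
#' Builds `length(spec@modeVariances)` displacement fields (3N-vectors) and
#' Gram-Schmidt-orthonormalizes them. A mode with planted block structure
#' moves each residue block rigidly along a common random direction with the
#' requested sign; unstructured modes are smooth random fields (low-frequency
#' mixtures so displacements are collective rather than per-atom noise).
#'
#' @param reference a [Frame-class] (defines N).
#' @param spec a [SyntheticSpec-class].
#' @return 3N x nModes matrix with orthonormal columns; block signs are
#'   preserved in the pre-orthogonalization construction.
#' @export
makeModes <- function(reference, spec) {
  n <- nResidues(reference)
  nModes <- length(spec@modeVariances)
  if (nModes > 3L * n) stop("parameter error: more modes than 3N degrees of freedom")
  withr::with_seed(spec@seed + 1L, {
    V <- matrix(0, 3L * n, nModes)
    for (k in seq_len(nModes)) {
      blocks <- if (k <= length(spec@modeBlocks)) spec@modeBlocks[[k]] else NULL
      field <- matrix(0, n, 3)
      if (!is.null(blocks)) {
        dir <- .unit(stats::rnorm(3))
        for (b in seq_len(nrow(blocks))) {
          ix <- which(reference@residueIndex >= blocks$from[b] &
                      reference@residueIndex <= blocks$to[b])
          field[ix, ] <- matrix(blocks$sign[b] * dir, length(ix), 3, byrow = TRUE)
        }
      } else {
        ## smooth low-frequency random field along the chain
        t <- seq(0, 1, length.out = n)
        for (ax in 1:3) {
          co <- stats::rnorm(4)
          field[, ax] <- co[1] * sin(pi * t) + co[2] * cos(pi * t) +
            co[3] * sin(2 * pi * t) + co[4] * cos(2 * pi * t)
        }
      }
      V[, k] <- as.numeric(t(field))   # x, y, z interleaved per residue
    }
    ## Gram-Schmidt
    for (k in seq_len(nModes)) {
      if (k > 1L)
        V[, k] <- V[, k] - V[, 1:(k - 1L), drop = FALSE] %*%
          crossprod(V[, 1:(k - 1L), drop = FALSE], V[, k])
      nv <- sqrt(sum(V[, k]^2))
      if (nv < 1e-12) stop("mode construction produced a degenerate field")
      V[, k] <- V[, k] / nv
    }
    V
  })
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Generate a synthetic trajectory, energy series and tunnel table
#'
#' Frame t of replica c is x(t) = R_t [x_ref + sum_k a_k(t) v_k] + s_t with
#' amplitudes a_k ~ Normal(basinMeans[c, k], modeVariances[k]), isotropic
#' per-atom Gaussian noise of sd `noiseSd`, and (when `rigidNuisance`) a
#' random rigid rotation R_t and translation s_t per frame. The energy series
#' is dG(t) = baseline + depth_c + sum_k w_k (a_k(t) - basinMeans[c, k])^2 +
#' Normal(0, energyNoiseSd) - minimal at the basin centers. The tunnel table
#' samples frames every `tunnelEveryNs` ns (excluding 0 ns) from each replica
#' for two groups with Bernoulli presence probabilities `tunnelProbs`. The
#' manifest records every latent value.
#'
#' @param spec a [SyntheticSpec-class].
#' @return List: `trajectory` ([Trajectory-class]), `energy`
#'   ([EnergySeries-class]), `tunnelTable` (data.frame frame, group, present),
#'   `manifest` (list: reference, modes, amplitudes, basinMeans,
#'   modeVariances, rigid transforms applied, energy latents, tunnel latents).
#' @export
generateSynthetic <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  ref <- makeReferenceChain(spec@nResidues, seed = spec@seed)
  V <- makeModes(ref, spec)
  nModes <- ncol(V)
  nf <- spec@nReplicas * spec@framesPerReplica
  n <- spec@nResidues
  withr::with_seed(spec@seed + 2L, {
    rep_id <- rep(seq_len(spec@nReplicas), each = spec@framesPerReplica)
    t_ns <- rep(seq_len(spec@framesPerReplica) - 1, spec@nReplicas)
    A <- matrix(NA_real_, nf, nModes)         # planted amplitudes
    for (k in seq_len(nModes))
      A[, k] <- stats::rnorm(nf, mean = spec@basinMeans[rep_id, k],
                             sd = sqrt(spec@modeVariances[k]))
    coords <- array(NA_real_, c(nf, n, 3))
    rigid <- vector("list", nf)
    refv <- as.numeric(t(ref@coords))         # 3N, x/y/z interleaved
    for (f in seq_len(nf)) {
      x <- refv + as.numeric(V %*% A[f, ])
      xyz <- matrix(x, ncol = 3, byrow = TRUE)
      if (spec@noiseSd > 0)
        xyz <- xyz + matrix(stats::rnorm(3 * n, sd = spec@noiseSd), n, 3)
      if (spec@rigidNuisance) {
        R <- .random_rotation()
        s <- stats::rnorm(3, sd = 5)
        xyz <- xyz %*% t(R) + matrix(s, n, 3, byrow = TRUE)
        rigid[[f]] <- list(rotation = R, translation = s)
      }
      coords[f, , ] <- xyz
    }
    ## without rigid nuisance all frames share the reference frame already
    traj <- Trajectory(coords, residueIndex = ref@residueIndex,
                       residueName = rep("ALA", n), element = rep("C", n),
                       replicaId = rep_id, timeNs = t_ns,
                       snapshotIntervalNs = 1, aligned = !spec@rigidNuisance,
                       referenceLabel = if (!spec@rigidNuisance)
                         "synthetic reference (no nuisance)" else NA_character_)
    dev2 <- (A - spec@basinMeans[rep_id, , drop = FALSE])^2
    dG <- spec@energyBaseline + spec@energyDepths[rep_id] +
      as.numeric(dev2 %*% spec@energyWeights) +
      stats::rnorm(nf, sd = spec@energyNoiseSd)
    energy <- new("EnergySeries",
                  frameLabels = data.frame(replica_id = rep_id, time_ns = t_ns),
                  dG = dG)
    ## tunnel table: every tunnelEveryNs ns (excluding 0 ns) from each replica
    keep <- t_ns > 0 & (t_ns %% spec@tunnelEveryNs == 0)
    frames01 <- which(keep) - 1L              # 0-based global indices
    groups <- c("group1", "group2")
    tunnel <- do.call(rbind, lapply(1:2, function(g) {
      data.frame(frame = frames01,
                 group = rep(groups[g], length(frames01)),
                 present = stats::rbinom(length(frames01), 1,
                                         spec@tunnelProbs[g]))
    }))
    manifest <- list(
      seed = spec@seed,
      nResidues = n, nReplicas = spec@nReplicas,
      framesPerReplica = spec@framesPerReplica,
      modeVariances = spec@modeVariances,
      basinMeans = spec@basinMeans,
      amplitudes = A,
      modes = V,
      reference = ref@coords,
      rigidNuisance = spec@rigidNuisance,
      noiseSd = spec@noiseSd,
      energy = list(baseline = spec@energyBaseline,
                    depths = spec@energyDepths,
                    weights = spec@energyWeights,
                    noiseSd = spec@energyNoiseSd),
      tunnelProbs = spec@tunnelProbs,
      tunnelCounts = vapply(split(tunnel$present, tunnel$group), sum,
                            numeric(1)),
      tunnelN = vapply(split(tunnel$present, tunnel$group), length,
                       numeric(1)))
    list(trajectory = traj, energy = energy, tunnelTable = tunnel,
         manifest = manifest)
  })
}

#' Write all synthetic outputs to a directory
#'
#' Multi-model PDB trajectory, energy CSV (replica_id, time_ns,
#' dG_kJ_per_mol), tunnel CSV (frame, group, present) and a JSON ground-truth
#' manifest (large matrices summarized by dimension).
#'
#' @param sim result of [generateSynthetic()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeSynthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMultimodelPDB(sim$trajectory, file.path(dir, "trajectory.pdb"))
  en <- cbind(sim$energy@frameLabels, dG_kJ_per_mol = sim$energy@dG)
  utils::write.csv(en, file.path(dir, "energy.csv"), row.names = FALSE)
  utils::write.csv(sim$tunnelTable, file.path(dir, "tunnel.csv"),
                   row.names = FALSE)
  man <- sim$manifest
  man$amplitudes <- dim(man$amplitudes)
  man$modes <- dim(man$modes)
  man$reference <- dim(man$reference)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
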