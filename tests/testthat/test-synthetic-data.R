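test_that("reference chain has exact Calpha spacing and is seed-deterministic", {
  ch <- makeReferenceChain(449, seed = 3)
  expect_equal(nResidues(ch), 449L)
  spacing <- sqrt(rowSums(diff(ch@coords)^2))
  expect_true(all(abs(spacing - 3.8) <= 0.01))
  # self-avoiding: no two non-consecutive atoms closer than a vdW contact
  d <- as.matrix(dist(ch@coords)); diag(d) <- Inf
  expect_gt(min(d[abs(row(d) - col(d)) > 1]), 2.5)
  # same seed, same chain; different seed, different orientation
  expect_identical(makeReferenceChain(449, seed = 3)@coords, ch@coords)
  expect_false(isTRUE(all.equal(makeReferenceChain(449, seed = 4)@coords,
                                ch@coords)))
  expect_error(makeReferenceChain(2), "nResidues")
})

test_that("mode fields are orthonormal and carry planted block sign structure", {
  spec <- syntheticSpec(nResidues = 30, seed = 5)
  ref <- makeReferenceChain(30, seed = 5)
  V <- makeModes(ref, spec)
  G <- crossprod(V)
  expect_lt(max(abs(G - diag(ncol(V)))), 1e-10)   # pairwise products & norms
  # more modes than 3N
  bad <- syntheticSpec(nResidues = 3, modeVariances = rep(1, 10) + 9:0, seed = 1)
  expect_error(makeModes(makeReferenceChain(3, seed = 1), bad), "parameter")
})

test_that("generator honors degenerate and default geometries", {
  # zero variances, zero noise, nuisance off -> every frame equals reference
  still <- syntheticSpec(nResidues = 12, nReplicas = 2, framesPerReplica = 5,
                         modeVariances = c(1e-30, 1e-31, 1e-32),
                         basinMeans = matrix(0, 2, 3), noiseSd = 0,
                         rigidNuisance = FALSE, energyDepths = c(0, 0),
                         seed = 6)
  sim0 <- generateSynthetic(still)
  ref <- makeReferenceChain(12, seed = 6)
  for (f in seq_len(nFrames(sim0$trajectory)))
    expect_lt(max(abs(sim0$trajectory@coords[f, , ] - ref@coords)), 1e-16 + 1e-10)

  # defaults: 3 replicas x 101 frames = 303 rows, 449 residues -> 1347 columns
  spec <- syntheticSpec(seed = 7)
  sim <- generateSynthetic(spec)
  expect_equal(nFrames(sim$trajectory), 303L)
  expect_equal(nResidues(sim$trajectory), 449L)
  cm <- buildCoordinateMatrix(superposeTrajectory(sim$trajectory))
  expect_equal(dim(cm@values), c(303L, 1347L))
  # energy and tunnel outputs have the right shape
  expect_length(sim$energy@dG, 303L)
  expect_equal(nrow(sim$tunnelTable), 120L)     # 60 sampled frames x 2 groups
  expect_equal(unname(sim$manifest$tunnelN), c(60, 60))
  # determinism under the spec seed
  sim2 <- generateSynthetic(spec)
  expect_identical(sim2$trajectory@coords, sim$trajectory@coords)
  expect_identical(sim2$energy@dG, sim$energy@dG)
})

test_that("planted amplitudes follow their law and rigid nuisance is removable", {
  # law of large numbers: sample variance of a_k at 1e4 frames within 1%
  spec <- syntheticSpec(nResidues = 6, nReplicas = 1, framesPerReplica = 1e4,
                        modeVariances = c(9, 4, 1),
                        basinMeans = matrix(0, 1, 3),
                        noiseSd = 0, rigidNuisance = FALSE, energyDepths = 0,
                        seed = 8)
  sim <- generateSynthetic(spec)
  v <- apply(sim$manifest$amplitudes, 2, var)
  expect_equal(v, c(9, 4, 1), tolerance = 0.03)
  # trajectory variance along each mode equals the amplitude variance
  cmraw <- buildCoordinateMatrix(sim$trajectory)
  proj <- sweep(cmraw@values, 2, colMeans(cmraw@values)) %*% sim$manifest$modes
  expect_equal(unname(apply(proj, 2, var)), c(9, 4, 1), tolerance = 0.03)

  # rigid nuisance: post-alignment analyses match the nuisance-off run
  base <- syntheticSpec(nResidues = 16, framesPerReplica = 40, noiseSd = 0.2,
                        rigidNuisance = FALSE, seed = 9)
  nuis <- base; nuis@rigidNuisance <- TRUE
  simA <- generateSynthetic(base)
  simB <- generateSynthetic(nuis)
  ref <- makeReferenceChain(16, seed = 9)
  alA <- superposeTrajectory(simA$trajectory, ref)
  alB <- superposeTrajectory(simB$trajectory, ref)
  # same seed: the planted amplitudes are identical, so aligned analyses agree
  # to sampling precision limited only by the noise realization differences
  expect_identical(simA$manifest$amplitudes, simB$manifest$amplitudes)
  rA <- rmsf(alA)$rmsf; rB <- rmsf(alB)$rmsf
  expect_equal(rA, rB, tolerance = 0.05)
  dA <- dccm(alA)@values; dB <- dccm(alB)@values
  expect_lt(mean(abs(dA - dB)), 0.05)
})

test_that("single-mode block trajectory yields the analytic +1/-1 DCCM", {
  spec <- syntheticSpec(nResidues = 10, nReplicas = 1, framesPerReplica = 50,
                        modeVariances = 4,
                        modeBlocks = list(data.frame(from = c(1, 6),
                                                     to = c(5, 10),
                                                     sign = c(1, -1))),
                        basinMeans = matrix(0, 1, 1), noiseSd = 0,
                        rigidNuisance = FALSE, energyDepths = 0,
                        energyWeights = 1, seed = 10)
  d <- dccm(generateSynthetic(spec)$trajectory)
  expect_equal(mean(d@values[1:5, 1:5]), 1, tolerance = 1e-9)
  expect_equal(mean(d@values[6:10, 6:10]), 1, tolerance = 1e-9)
  expect_equal(mean(d@values[1:5, 6:10]), -1, tolerance = 1e-9)
})

test_that("energy surface has its minima at the basin centers", {
  spec <- syntheticSpec(nResidues = 10, framesPerReplica = 60,
                        energyNoiseSd = 0, seed = 11)
  sim <- generateSynthetic(spec)
  rep_id <- sim$energy@frameLabels$replica_id
  dev2 <- (sim$manifest$amplitudes -
           sim$manifest$basinMeans[rep_id, ])^2
  expected <- 95 + sim$manifest$energy$depths[rep_id] +
    as.numeric(dev2 %*% sim$manifest$energy$weights)
  expect_equal(sim$energy@dG, expected, tolerance = 1e-10)
  # at the basin center dev2 = 0, so dG is bounded below by baseline + depth
  for (r in 1:3)
    expect_gte(min(sim$energy@dG[rep_id == r]),
               95 + sim$manifest$energy$depths[r] - 1e-9)
})

test_that("tunnel sampling frequency matches the derived test power", {
  # Oracle (200k-rep binomial simulation of the pooled z-test at the planted
  # probabilities 23/60 vs 38/60, n = 60): P(p < 0.01) = 0.555, P(p < 0.05)
  # = 0.802. Frequencies over a fixed 60-seed panel must sit inside a wide
  # binomial band around those values.
  ps <- vapply(1:60, function(s) {
    spec <- syntheticSpec(nResidues = 6, framesPerReplica = 101, seed = s)
    tab <- generateSynthetic(spec)$tunnelTable
    tryCatch(tunnelPresenceTest(tab)@pTwoSided, error = function(e) 1)
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.01) - 0.555), 0.20)
  expect_gte(mean(ps < 0.05), 0.60)
})

test_that("synthetic outputs write to disk and re-attach cleanly", {
  dir <- withr::local_tempdir()
  spec <- syntheticSpec(nResidues = 15, framesPerReplica = 21, seed = 12)
  sim <- generateSynthetic(spec)
  writeSynthetic(sim, dir)
  expect_true(all(file.exists(file.path(dir,
    c("trajectory.pdb", "energy.csv", "tunnel.csv", "manifest.json")))))
  back <- readMultimodelPDB(file.path(dir, "trajectory.pdb"))
  expect_equal(nFrames(back), 63L)
  expect_equal(frameLabels(back), frameLabels(sim$trajectory))
  es <- attachEnergy(frameLabels(back), file.path(dir, "energy.csv"))
  expect_equal(es@dG, sim$energy@dG, tolerance = 1e-12)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 12L)
})
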