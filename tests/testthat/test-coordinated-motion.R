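test_that("DCCM matches its definition, the brute-force oracle, and bounds", {
  set.seed(51)
  coords <- array(rnorm(50 * 20 * 3, sd = 2), c(50, 20, 3))
  traj <- Trajectory(coords, residueIndex = 1:20, aligned = TRUE)
  d <- dccm(traj)
  expect_equal(unname(diag(d@values)), rep(1, 20))
  expect_lt(max(abs(d@values - t(d@values))), 1e-12)
  expect_true(all(abs(d@values) <= 1 + 1e-9))
  # exhaustive double-loop recomputation to 1e-12
  expect_equal(d@values, brute_force_dccm(coords), tolerance = 1e-12,
               ignore_attr = TRUE)

  # identical displacement series -> +1; negated -> -1
  base <- matrix(rnorm(30 * 3), 30, 3)
  disp <- matrix(rnorm(30 * 3), 30, 3)
  c3 <- array(NA_real_, c(30, 3, 3))
  for (f in 1:30) {
    c3[f, 1, ] <- base[1, ] + disp[f, ]
    c3[f, 2, ] <- base[2, ] + disp[f, ]      # identical series
    c3[f, 3, ] <- base[3, ] - disp[f, ]      # negated series
  }
  dc <- dccm(Trajectory(c3, residueIndex = 1:3, aligned = TRUE))
  expect_equal(dc@values[1, 2], 1, tolerance = 1e-12)
  expect_equal(dc@values[1, 3], -1, tolerance = 1e-12)

  # independent-noise residues at 1e4 frames: |C_ij| < 0.05 off-diagonal
  big <- array(rnorm(1e4 * 6 * 3), c(1e4, 6, 3))
  db <- dccm(Trajectory(big, residueIndex = 1:6, aligned = TRUE))
  expect_lt(max(abs(db@values[upper.tri(db@values)])), 0.05)

  # zero-variance residue: flagged, zero off-diagonal, unit diagonal
  frz <- coords; frz[, 5, ] <- rep(coords[1, 5, ], each = 50)
  dz <- dccm(Trajectory(frz, residueIndex = 1:20, aligned = TRUE))
  expect_identical(dz@zeroVarianceResidues, 5L)
  expect_equal(unname(dz@values[5, -5]), rep(0, 19))
  expect_equal(dz@values[5, 5], 1)
})

test_that("DCCM is invariant under a global rotation applied before alignment", {
  set.seed(52)
  ref <- makeReferenceChain(15, seed = 3)
  coords <- array(rep(ref@coords, each = 40), c(40, 15, 3)) +
    array(rnorm(40 * 45, sd = 0.5), c(40, 15, 3))
  traj <- Trajectory(coords, residueIndex = 1:15)
  R <- random_rotation()
  rot <- traj
  for (f in 1:40) rot@coords[f, , ] <- traj@coords[f, , ] %*% t(R)
  d1 <- dccm(superposeTrajectory(traj, ref))
  d2 <- dccm(superposeTrajectory(rot, ref))
  expect_equal(d1@values, d2@values, tolerance = 1e-8)
})

test_that("DCCM equals the normalized residue-block trace of the 3N covariance", {
  set.seed(53)
  coords <- array(rnorm(35 * 8 * 3), c(35, 8, 3))
  traj <- Trajectory(coords, residueIndex = 1:8, aligned = TRUE)
  cm <- buildCoordinateMatrix(traj)
  S <- cov(cm@values) * (35 - 1) / 35        # population covariance of 3N coords
  G <- matrix(NA_real_, 8, 8)
  for (i in 1:8) for (j in 1:8)
    G[i, j] <- sum(diag(S[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]))
  expected <- G / sqrt(outer(diag(G), diag(G)))
  expect_equal(dccm(traj)@values, expected, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("block summarization recovers planted anti-correlated blocks", {
  set.seed(54)
  # rank-1 displacement along one block-structured mode: +1 within blocks,
  # -1 between them (plus negligible numeric noise)
  spec <- syntheticSpec(nResidues = 20, nReplicas = 1, framesPerReplica = 60,
                        modeVariances = 4,
                        modeBlocks = list(data.frame(from = c(1, 11),
                                                     to = c(10, 20),
                                                     sign = c(1, -1))),
                        basinMeans = matrix(0, 1, 1),
                        noiseSd = 0, rigidNuisance = FALSE,
                        energyDepths = 0, energyWeights = 1, seed = 12)
  sim <- generateSynthetic(spec)
  d <- dccm(sim$trajectory)
  expect_equal(mean(d@values[1:10, 1:10]), 1, tolerance = 1e-9)
  expect_equal(mean(d@values[1:10, 11:20]), -1, tolerance = 1e-9)

  blocks <- dccmBlocks(d, threshold = 0.8)
  expect_equal(nrow(blocks), 3L)
  expect_equal(sum(blocks$sign == 1), 2L)    # one positive pair per block
  expect_equal(sum(blocks$sign == -1), 1L)   # one negative inter-block pair
  neg <- blocks[blocks$sign == -1, ]
  expect_equal(c(neg$from_1, neg$to_1, neg$from_2, neg$to_2), c(1, 10, 11, 20))
  expect_equal(neg$mean_abs_c, 1, tolerance = 1e-9)

  # identity-like matrix -> nothing beyond the diagonal
  eye <- new("DCCMatrix", values = diag(20), residueLabels = 1:20)
  expect_equal(nrow(dccmBlocks(eye, threshold = 0.5)), 0L)

  # threshold 0.99 on noisy data -> empty
  noisy <- dccm(Trajectory(array(rnorm(40 * 20 * 3), c(40, 20, 3)),
                           residueIndex = 1:20, aligned = TRUE))
  expect_equal(nrow(dccmBlocks(noisy, threshold = 0.99)), 0L)
})

test_that("porcupine fields scale eigenvector triplets and export round-trips", {
  set.seed(55)
  ref <- makeReferenceChain(12, seed = 2)
  # unit loading on residue 5's x only, scale 10 -> single arrow (10, 0, 0)
  L <- matrix(0, 36, 2); L[13, 1] <- 1; L[2, 2] <- 1
  res <- new("EssentialDynamicsResult",
             eigenvalues = c(2, 1), varianceProportion = c(2, 1) / 3,
             cumulativeProportion = cumsum(c(2, 1) / 3),
             scores = matrix(0, 4, 2), loadings = L, kRetained = 2L,
             standardized = FALSE,
             columnLabels = data.frame(residue_index = rep(1:12, each = 3),
                                       axis = rep(c("x", "y", "z"), 12)),
             frameLabels = data.frame(replica_id = 1, time_ns = 0:3))
  f <- porcupineField(res, 1L, ref, scale = 10)
  expect_equal(f@arrows[5, ], c(10, 0, 0))
  expect_equal(unname(f@magnitude[-5]), rep(0, 11))

  # zero eigenvector -> all-zero arrows
  res0 <- res; res0@loadings[, 1] <- 0
  expect_true(all(porcupineField(res0, 1L, ref, scale = 5)@magnitude == 0))

  # arrow magnitudes equal scale * per-residue loading norms, random vectors
  v <- rnorm(36); v <- v / sqrt(sum(v^2))
  resr <- res; resr@loadings[, 1] <- v
  fr <- porcupineField(resr, 1L, ref, scale = 3.7)
  norms <- sqrt(rowSums(matrix(v, ncol = 3, byrow = TRUE)^2))
  expect_equal(fr@magnitude, 3.7 * norms, tolerance = 1e-12)

  # default scale: longest arrow is 10 A
  expect_equal(max(porcupineField(resr, 1L, ref)@magnitude), 10, tolerance = 1e-9)

  # out-of-range component
  expect_error(porcupineField(res, 3L, ref), "parameter error")

  # CSV round-trip exact; BILD parse-back: one arrow per residue, tip = base + arrow
  csv <- withr::local_tempfile(fileext = ".csv")
  exportArrows(fr, csv, "csv")
  back <- readArrowsCSV(csv)
  expect_equal(back@arrows, fr@arrows, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(nrow(back@arrows), 12L)

  bild <- withr::local_tempfile(fileext = ".bild")
  exportArrows(fr, bild, "bild")
  lines <- grep("^\\.arrow", readLines(bild), value = TRUE)
  expect_length(lines, 12L)
  nums <- do.call(rbind, lapply(strsplit(lines, "\\s+"), function(p)
    as.numeric(p[2:7])))
  expect_equal(nums[, 4:6], unname(fr@base + fr@arrows), tolerance = 1e-5)

  expect_error(exportArrows(fr, csv, "xyz"), "parameter error")

  # arrow-difference table between two variants over one reference
  f2 <- porcupineField(res, 2L, ref, scale = 10)
  tab <- arrowDifferenceTable(fr, f2)
  expect_equal(nrow(tab), 12L)
  expect_equal(tab$diff_magnitude,
               sqrt(rowSums((fr@arrows - f2@arrows)^2)), tolerance = 1e-12)
})
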