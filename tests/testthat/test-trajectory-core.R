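test_that("multi-model PDB writing and reading round-trips frames and coordinates", {
  set.seed(11)
  coords <- array(rnorm(3 * 2 * 3, sd = 5), c(3, 2, 3))
  traj <- Trajectory(coords, residueIndex = c(4L, 9L),
                     residueName = c("GLY", "TRP"))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeMultimodelPDB(traj, path)
  back <- readMultimodelPDB(path)
  expect_equal(nFrames(back), 3L)
  expect_identical(residueIndex(back), c(4L, 9L))
  # format precision is 0.001 A
  expect_lt(max(abs(back@coords - traj@coords)), 0.001 + 1e-12)
  expect_equal(frameLabels(back), frameLabels(traj))

  # 101 MODEL blocks -> 101 frames
  t101 <- Trajectory(array(rnorm(101 * 2 * 3), c(101, 2, 3)),
                     residueIndex = 1:2)
  writeMultimodelPDB(t101, path)
  expect_equal(nFrames(readMultimodelPDB(path)), 101L)
})

test_that("PDB reader and writer reject malformed input", {
  set.seed(12)
  traj <- Trajectory(array(rnorm(2 * 6 * 3), c(2, 6, 3)), residueIndex = 1:6)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeMultimodelPDB(traj, path)

  # drop residue 5's Calpha from model 2 -> structural error naming both
  lines <- readLines(path)
  atom_lines <- grep("^ATOM", lines)
  model2_atoms <- atom_lines[7:12]           # 6 atoms per model
  res5_in_m2 <- model2_atoms[5]
  writeLines(lines[-res5_in_m2], path)
  expect_error(readMultimodelPDB(path), "model 2.*residue 5")

  # empty trajectory and coordinate overflow
  expect_error(writeMultimodelPDB(
    Trajectory(array(numeric(0), c(0, 6, 3)), residueIndex = 1:6), path),
    "empty")
  big <- Trajectory(array(c(10500, rnorm(17)), c(1, 6, 3)), residueIndex = 1:6)
  expect_error(writeMultimodelPDB(big, path), "format-overflow")
})

test_that("replica concatenation preserves counts, content and boundaries", {
  set.seed(13)
  mk <- function(nf) Trajectory(array(rnorm(nf * 4 * 3), c(nf, 4, 3)),
                                residueIndex = 1:4)
  reps <- list(mk(101), mk(101), mk(101))
  cat3 <- concatenateReplicas(reps)
  expect_equal(nFrames(cat3), 303L)
  # 0 ns frames of replicas 1-3 land at global 0-based indices 0, 101, 202
  zero_ns <- which(timeNs(cat3) == 0) - 1L
  expect_identical(zero_ns, c(0L, 101L, 202L))
  expect_equal(cat3@coords[102, , ], reps[[2]]@coords[1, , ])

  # single replica is passed through unchanged
  one <- concatenateReplicas(list(reps[[1]]))
  expect_identical(one@coords, reps[[1]]@coords)

  # 50 + 51 frames -> 101, boundary preserved in labels
  ab <- concatenateReplicas(list(mk(50), mk(51)))
  expect_equal(nFrames(ab), 101L)
  expect_identical(replicaId(ab), rep(1:2, c(50L, 51L)))

  # mismatched residue sets fail
  bad <- Trajectory(array(rnorm(5 * 3 * 3), c(5, 3, 3)), residueIndex = 1:3)
  expect_error(concatenateReplicas(list(reps[[1]], bad)), "consistency")
})

test_that("Kabsch fit recovers planted rigid transforms and matches a brute-force oracle", {
  set.seed(14)
  ref <- matrix(rnorm(12 * 3, sd = 4), 12, 3)

  # identity case
  fit0 <- kabschFit(ref, ref)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)

  # mobile = reference rotated 90 deg about z, translated (1,2,3):
  # recovered transform composes to identity
  R90 <- rotation_z(pi / 2)
  mobile <- ref %*% t(R90) + matrix(c(1, 2, 3), 12, 3, byrow = TRUE)
  fit <- kabschFit(mobile, ref)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$rotation %*% R90, diag(3), tolerance = 1e-8)
  expect_equal(applySuperposition(fit, mobile), ref, tolerance = 1e-8)

  # planar 4-point set with per-point offsets: rmsd equals the exhaustive
  # rotation-grid oracle
  refp <- cbind(matrix(rnorm(8, sd = 3), 4, 2), 0)
  mob <- refp + cbind(matrix(rnorm(8, sd = 0.4), 4, 2), 0)
  expect_equal(kabschFit(mob, refp)$rmsd,
               brute_force_rmsd_planar(mob, refp), tolerance = 1e-6)

  # error / degenerate cases
  expect_error(kabschFit(ref[1:2, ], ref[1:2, ]), "insufficient")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_warning(kabschFit(line, line), "degenerate")
})

test_that("Kabsch rotations are proper orthonormal matrices for random inputs", {
  set.seed(15)
  for (i in 1:25) {
    a <- matrix(rnorm(15, sd = 3), 5, 3)
    b <- matrix(rnorm(15, sd = 3), 5, 3)
    R <- kabschFit(a, b)$rotation
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-8)
    expect_equal(det(R), 1, tolerance = 1e-8)
  }
})

test_that("trajectory superposition removes planted rigid motion and never hurts", {
  set.seed(16)
  ref <- makeReferenceChain(20, seed = 5)
  traj <- rigid_copies_trajectory(ref, 15)
  al <- superposeTrajectory(traj, ref)
  expect_true(isAligned(al))
  expect_lt(max(abs(sweep(al@coords, c(2, 3), ref@coords))), 1e-8)

  # idempotence on already-aligned data
  al2 <- superposeTrajectory(al, ref)
  expect_lt(max(abs(al2@coords - al@coords)), 1e-10)

  # minimizer property: per-frame RMSD never increases
  noisy <- traj
  noisy@coords <- noisy@coords + array(rnorm(length(noisy@coords)), dim(noisy@coords))
  before <- rmsdToReference(noisy, ref)
  after <- rmsdToReference(superposeTrajectory(noisy, ref), ref)
  expect_true(all(after <= before + 1e-12))
})

test_that("coordinate matrix has the x/y/z-per-residue layout and reshapes back", {
  set.seed(17)
  traj <- Trajectory(array(rnorm(10 * 449 * 3), c(10, 449, 3)),
                     residueIndex = 1:449, aligned = TRUE)
  cm <- buildCoordinateMatrix(traj)
  expect_equal(ncol(cm@values), 1347L)
  expect_equal(nrow(cm@values), 10L)
  expect_identical(colnames(cm@values)[1:4], c("r1_x", "r1_y", "r1_z", "r2_x"))

  # row 7 reshaped to N x 3 equals frame 7
  expect_equal(matrix(cm@values[7, ], ncol = 3, byrow = TRUE),
               traj@coords[7, , ], ignore_attr = TRUE)

  # 1 residue, 1 frame -> 1 x 3
  tiny <- Trajectory(array(rnorm(3), c(1, 1, 3)), aligned = TRUE)
  expect_equal(dim(suppressWarnings(buildCoordinateMatrix(tiny))@values), c(1L, 3L))

  # unaligned trajectory warns, does not error
  una <- Trajectory(array(rnorm(6 * 3), c(2, 3, 3)), residueIndex = 1:3)
  expect_warning(buildCoordinateMatrix(una), "provenance")

  # CSV dialect round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  writeCoordinateMatrixCSV(cm, path)
  back <- readCoordinateMatrixCSV(path)
  expect_equal(back@values, cm@values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back@frameLabels, cm@frameLabels)
})
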