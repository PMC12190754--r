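## Independent oracles and small generators shared across the suite.
## Oracles deliberately use the dumbest correct formulation (double loops,
## grids, closed forms) so they stay independent of the package code paths.

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Brute-force optimal-fit RMSD for PLANAR point sets (all z = 0): the optimal
## rotation is then about z, so a fine 1-D angle grid plus centroid matching
## is exhaustive. Used against kabschFit on 4-point planar sets.
brute_force_rmsd_planar <- function(mobile, reference, n_grid = 720000) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  thetas <- seq(0, 2 * pi, length.out = n_grid)
  ## rmsd^2(theta) = mean|a R(theta)^T - b|^2 expands to
  ## c0 - 2/n (cos t * s_cos + sin t * s_sin) with
  s_cos <- sum(a[, 1] * b[, 1] + a[, 2] * b[, 2])
  s_sin <- sum(a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c0 <- mean(rowSums(a^2)) + mean(rowSums(b^2))
  r2 <- c0 - (2 / nrow(a)) * (cos(thetas) * s_cos + sin(thetas) * s_sin)
  sqrt(max(0, min(r2)))
}

## Exhaustive N^2 double-loop DCCM.
brute_force_dccm <- function(coords) {
  nf <- dim(coords)[1]; nr <- dim(coords)[2]
  mu <- apply(coords, c(2, 3), mean)
  C <- matrix(NA_real_, nr, nr)
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    di <- sweep(coords[, i, , drop = TRUE], 2, mu[i, ])
    dj <- sweep(coords[, j, , drop = TRUE], 2, mu[j, ])
    num <- mean(rowSums(di * dj))
    C[i, j] <- num / sqrt(mean(rowSums(di^2)) * mean(rowSums(dj^2)))
  }
  C
}

## Exposed area of two equal overlapping Shrake-Rupley spheres of expanded
## radius R at center distance d (< 2R): each sphere loses the spherical cap
## of height h = R - d/2 cut by the other's radius-R ball.
two_sphere_exposed_area <- function(R, d) {
  h <- R - d / 2
  per_sphere <- 4 * pi * R^2 - 2 * pi * R * h
  2 * per_sphere
}

## Label agreement maximized over cluster relabelings (Hungarian assignment).
label_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  la <- sort(unique(a)); lb <- sort(unique(b))
  k <- max(length(la), length(lb))
  cost <- matrix(0, k, k)
  for (i in seq_along(la)) for (j in seq_along(lb))
    cost[i, j] <- sum(a == la[i] & b == lb[j])
  perm <- clue::solve_LSAP(cost, maximum = TRUE)
  sum(cost[cbind(seq_len(k), perm)]) / length(a)
}

## Largest principal angle (degrees) between the column spans of two
## orthonormal-ized bases.
max_principal_angle_deg <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(s)))) * 180 / pi
}

## Small rigid-copies trajectory: every frame is `ref` under a random rigid
## transform (ground truth for superposition tests).
rigid_copies_trajectory <- function(ref, n_frames) {
  n <- nrow(ref@coords)
  coords <- array(NA_real_, c(n_frames, n, 3))
  for (f in seq_len(n_frames)) {
    R <- random_rotation()
    s <- rnorm(3, sd = 10)
    coords[f, , ] <- ref@coords %*% t(R) + matrix(s, n, 3, byrow = TRUE)
  }
  Trajectory(coords, residueIndex = ref@residueIndex)
}
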