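test_that("energy attachment aligns, reorders, and reports mismatches by frame", {
  fl <- data.frame(replica_id = rep(1:2, each = 3), time_ns = rep(0:2, 2))
  en <- cbind(fl, dG_kJ_per_mol = 100 + 1:6)
  es <- attachEnergy(fl, en)
  expect_equal(es@dG, 100 + 1:6)

  # permuted rows are reordered back by their labels
  perm <- en[sample(6), ]
  expect_equal(attachEnergy(fl, perm)@dG, 100 + 1:6)

  # one missing frame -> error naming (replica, time)
  expect_error(attachEnergy(fl, en[-4, ]), "replica 2.*time 0")
  # extra frame -> error
  extra <- rbind(en, data.frame(replica_id = 3, time_ns = 0, dG_kJ_per_mol = 1))
  expect_error(attachEnergy(fl, extra), "extra")
})

test_that("landscape interpolation reproduces data and finds planted basins", {
  set.seed(61)
  # constant energy -> flat landscape everywhere defined
  sc <- matrix(runif(400, -5, 5), 200, 2)
  flat <- buildLandscape(sc, rep(42, 200), gridN = 40)
  defined <- !is.na(flat@dGGrid)
  expect_gt(sum(defined), 0)
  expect_equal(unname(flat@dGGrid[defined]), rep(42, sum(defined)),
               tolerance = 1e-9)

  # interpolation reproduces the input dG at the data points exactly
  z <- sin(sc[, 1]) + sc[, 2]^2
  ls <- buildLandscape(sc, z, gridN = 40)
  expect_equal(landscapeAt(ls, sc[, 1], sc[, 2]), z, tolerance = 1e-12)

  # planted quadratic bowl, 500 frames: a piecewise-linear interpolant of a
  # convex bowl attains its minimum at the sample nearest the center, so the
  # grid minimum must land within one grid spacing of that sample (and that
  # sample near (a, b) at this sampling density)
  a <- 1.3; b <- -0.7
  sc2 <- matrix(runif(1000, -4, 4), 500, 2)
  bowl <- (sc2[, 1] - a)^2 + (sc2[, 2] - b)^2
  lb <- buildLandscape(sc2, bowl, gridN = 100)
  mins <- landscapeMinima(lb)
  h1 <- diff(lb@gridPC1[1:2]); h2 <- diff(lb@gridPC2[1:2])
  nearest <- sc2[which.min(bowl), ]
  expect_lte(abs(mins$pc1[1] - nearest[1]), h1 + 1e-9)
  expect_lte(abs(mins$pc2[1] - nearest[2]), h2 + 1e-9)
  expect_lt(sqrt((nearest[1] - a)^2 + (nearest[2] - b)^2), 0.5)

  # two planted basins -> exactly two local minima, each within one grid
  # spacing of its basin's in-sample minimum
  c1 <- c(-2, 0); c2 <- c(2, 0)
  d1 <- (sc2[, 1] - c1[1])^2 + (sc2[, 2] - c1[2])^2
  d2 <- (sc2[, 1] - c2[1])^2 + (sc2[, 2] - c2[2])^2
  two <- pmin(d1, d2)
  lt <- buildLandscape(sc2, two, gridN = 100)
  m2 <- landscapeMinima(lt)
  expect_equal(nrow(m2), 2L)
  found <- m2[order(m2$pc1), ]
  near1 <- sc2[which.min(d1), ]; near2 <- sc2[which.min(d2), ]
  expect_lte(abs(found$pc1[1] - near1[1]), h1 + 1e-9)
  expect_lte(abs(found$pc2[1] - near1[2]), h2 + 1e-9)
  expect_lte(abs(found$pc1[2] - near2[1]), h1 + 1e-9)
  expect_lte(abs(found$pc2[2] - near2[2]), h2 + 1e-9)

  # landscape minimum never undercuts the observed minimum
  expect_gte(min(lt@dGGrid, na.rm = TRUE), min(two) - 1e-9)

  # degenerate collinear scores
  line <- cbind(1:10, 2 * (1:10))
  expect_error(buildLandscape(line, rnorm(10)), "degeneracy")
})

test_that("landscape statistics mirror the descriptive-table layout", {
  fl <- data.frame(replica_id = rep(1:3, each = 4), time_ns = rep(0:3, 3))
  # constant series: all averages equal, sd 0
  cst <- new("EnergySeries", frameLabels = fl, dG = rep(7, 12))
  st <- landscapeStats(cst)
  expect_equal(st$average, 7); expect_equal(st$sd, 0)
  expect_equal(st$minimum, 7); expect_equal(st$maximum, 7)
  expect_equal(st$trajectory2_average, 7)

  # random series equals brute-force recomputation, incl. per-cluster means
  set.seed(62)
  v <- rnorm(12, 100, 10)
  es <- new("EnergySeries", frameLabels = fl, dG = v)
  labs <- rep(c(0L, 1L), 6)
  model <- new("ClusterModel", k = 2L, labels = labs,
               centers = matrix(0, 2, 2), meanSilhouette = 0.5,
               silhouetteByK = data.frame(k = 2, mean_silhouette = 0.5),
               seed = 1L, noStrongStructure = FALSE)
  st2 <- landscapeStats(es, model, label = "case")
  expect_equal(st2$average, mean(v), tolerance = 1e-12)
  expect_equal(st2$minimum, min(v)); expect_equal(st2$maximum, max(v))
  expect_equal(st2$trajectory1_average, mean(v[1:4]), tolerance = 1e-12)
  expect_equal(st2$trajectory3_average, mean(v[9:12]), tolerance = 1e-12)
  expect_equal(st2$cluster0_average, mean(v[labs == 0L]), tolerance = 1e-12)
  # layout: average / minimum / maximum / per-trajectory averages present
  expect_true(all(c("average", "minimum", "maximum", "trajectory1_average",
                    "trajectory2_average", "trajectory3_average")
                  %in% names(st2)))
})

test_that("pooled two-proportion Z-test matches the printed tunnel comparison", {
  # the tunnel-presence counts: 23/60 vs 38/60
  zt <- twoProportionZTest(23, 60, 38, 60)
  expect_equal(round(zt@pTwoSided, 4), 0.0062)
  expect_equal(round(zt@pooled, 2), 0.51)
  expect_equal(round(zt@p1, 2), 0.38)
  expect_equal(round(zt@p2, 2), 0.63)
  expect_equal(round(abs(zt@z), 2), 2.74)
  expect_equal(round(zt@se, 2), 0.09)

  # equal proportions -> z = 0, p = 1
  z0 <- twoProportionZTest(30, 60, 30, 60)
  expect_equal(z0@z, 0); expect_equal(z0@pTwoSided, 1)

  # random valid counts vs an independent CDF recomputation
  set.seed(63)
  for (i in 1:20) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    s1 <- sample(0:n1, 1); s2 <- sample(0:n2, 1)
    if ((s1 + s2) %in% c(0, n1 + n2)) next
    zt <- twoProportionZTest(s1, n1, s2, n2)
    ph <- (s1 + s2) / (n1 + n2)
    zz <- (s2 / n2 - s1 / n1) / sqrt(ph * (1 - ph) * (1 / n1 + 1 / n2))
    expect_equal(zt@pTwoSided, 2 * (1 - pnorm(abs(zz))), tolerance = 1e-12)
    # antisymmetry in group order
    sw <- twoProportionZTest(s2, n2, s1, n1)
    expect_equal(sw@z, -zt@z, tolerance = 1e-12)
    expect_equal(sw@pTwoSided, zt@pTwoSided, tolerance = 1e-12)
  }

  # p decreases monotonically as the proportion gap grows at fixed n
  ps <- vapply(30:55, function(s) twoProportionZTest(25, 60, s, 60)@pTwoSided,
               numeric(1))
  expect_true(all(diff(ps) < 0))

  # degenerate pooled proportions
  expect_error(twoProportionZTest(0, 10, 0, 10), "degenerate")
  expect_error(twoProportionZTest(10, 10, 10, 10), "degenerate")

  # aggregation from a tunnel table reproduces the counts
  tab <- data.frame(frame = rep(1:60, 2),
                    group = rep(c("wt", "mut"), each = 60),
                    present = c(rep(1, 23), rep(0, 37), rep(1, 38), rep(0, 22)))
  zt2 <- tunnelPresenceTest(tab)
  expect_equal(zt2@successes1, 23L); expect_equal(zt2@successes2, 38L)
  expect_equal(zt2@pTwoSided, twoProportionZTest(23, 60, 38, 60)@pTwoSided)
})
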