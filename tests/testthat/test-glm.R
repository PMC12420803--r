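## Build a list of 3D subject maps from a subjects x voxels matrix.
mapsFromMatrix <- function(M, dm = c(4, 4, 4), voxelSizeMm = 3) {
  lapply(seq_len(nrow(M)), function(i)
    statMap(array(M[i, ], dim = dm), voxelSizeMm = voxelSizeMm))
}

test_that("voxelwise GLM reduces to the two-sample pooled t-test", {
  set.seed(31)
  n <- 14
  grp <- rep(c(0, 1), each = n / 2)
  M <- matrix(rnorm(n * 64), n)
  M[grp == 1, 5] <- M[grp == 1, 5] + 1.2
  des <- designMatrix(cbind(1, grp), c(0, 1))
  tmap <- fitVoxelwiseGlm(mapsFromMatrix(M), des)
  want <- apply(M, 2, function(y)
    -stats::t.test(y ~ grp, var.equal = TRUE)$statistic)
  expect_equal(as.vector(imgData(tmap)), unname(want), tolerance = 1e-10)
  expect_equal(tmap@df, n - 2)

  ## swapping group labels flips the t-map sign exactly
  des2 <- designMatrix(cbind(1, 1 - grp), c(0, 1))
  tmap2 <- fitVoxelwiseGlm(mapsFromMatrix(M), des2)
  expect_equal(imgData(tmap2), -imgData(tmap), tolerance = 1e-12)

  ## rank deficiency is an error naming the offending column
  desBad <- designMatrix(cbind(a = 1, group = grp, twice = 2 * grp),
                         c(0, 1, 0))
  expect_error(fitVoxelwiseGlm(mapsFromMatrix(M), desBad), "twice")
})

test_that("site fixed effects absorb per-site constant shifts", {
  set.seed(32)
  n <- 16
  grp <- rep(c(0, 1), 8)
  site <- rep(c(0, 1), each = 8)
  M <- matrix(rnorm(n * 27), n)
  X <- cbind(1, grp, site)
  des <- designMatrix(X, c(0, 1, 0))
  t1 <- fitVoxelwiseGlm(mapsFromMatrix(M, c(3, 3, 3)), des)
  M2 <- M + 5 * site   # constant added to every map of site 1
  t2 <- fitVoxelwiseGlm(mapsFromMatrix(M2, c(3, 3, 3)), des)
  expect_equal(imgData(t1), imgData(t2), tolerance = 1e-9)
})

test_that("TFCE matches its discrete-sum closed forms", {
  ## all-zero map -> all-zero TFCE
  z <- statMap(array(0, dim = c(4, 4, 4)))
  expect_true(all(imgData(tfceTransform(z)) == 0))

  ## isolated voxel of height a: sum over threshold slabs of the midpoint
  ## height to the power H, times dh, with extent 1
  a <- 2.4; E <- 0.5; H <- 2
  m <- statMap(array(0, dim = c(7, 7, 7)))
  m@data[4, 4, 4] <- a
  dh <- a / 100
  got <- imgData(tfceTransform(m, E = E, H = H, dh = dh))[4, 4, 4]
  want <- sum((dh * (1:100 - 0.5))^H * dh)
  expect_equal(got, want, tolerance = 1e-10)
  ## and within 1% of the continuous closed form a^(H+1)/(H+1)
  expect_lt(abs(got - a^3 / 3) / (a^3 / 3), 0.01)

  ## negative values are transformed on the negated map, with sign kept
  m@data[2, 2, 2] <- -a
  got2 <- imgData(tfceTransform(m, E = E, H = H, dh = dh))
  expect_equal(got2[2, 2, 2], -want, tolerance = 1e-10)

  ## scaling the map by lambda (with dh rescaled) scales TFCE by
  ## lambda^(H+1) and preserves the voxel ordering
  set.seed(33)
  r <- statMap(array(rnorm(125), dim = c(5, 5, 5)))
  lam <- 3
  f1 <- imgData(tfceTransform(r, dh = 0.02))
  r2 <- statMap(imgData(r) * lam, affine = imgAffine(r))
  f2 <- imgData(tfceTransform(r2, dh = 0.02 * lam))
  expect_equal(f2, lam^(H + 1) * f1, tolerance = 1e-8)
  nz <- f1 != 0
  expect_gt(cor(f1[nz], f2[nz], method = "spearman"), 0.99999)
})

test_that("permutation inference ranks extreme effects at the minimum p", {
  set.seed(34)
  n <- 12
  grp <- rep(c(0, 1), each = n / 2)
  M <- matrix(rnorm(n * 27, sd = 0.1), n)
  M[grp == 1, ] <- M[grp == 1, ] + 50   # overwhelming global effect
  des <- designMatrix(cbind(1, grp), c(0, 1))
  inf <- permutationInference(mapsFromMatrix(M, c(3, 3, 3)), des,
                              nPerm = 199, seed = 7)
  ## the observed maxima beat every permuted maximum
  expect_equal(min(imgData(inf@fweP), na.rm = TRUE), 1 / 200)
  expect_true(all(inf@sigMaskPos | inf@sigMaskNeg))
  expect_false(any(inf@sigMaskPos & inf@sigMaskNeg))
  expect_true(all(imgData(inf@fweP) >= 0 & imgData(inf@fweP) <= 1,
                  na.rm = TRUE))

  ## determinism under a fixed seed
  inf2 <- permutationInference(mapsFromMatrix(M, c(3, 3, 3)), des,
                               nPerm = 199, seed = 7)
  expect_identical(imgData(inf@fwePTfce), imgData(inf2@fwePTfce))
})

test_that("few distinct permutations trigger exhaustive enumeration", {
  set.seed(35)
  n <- 5
  M <- matrix(rnorm(n * 8), n)
  des <- designMatrix(cbind(1, c(0, 0, 1, 1, 1)), c(0, 1))
  expect_message(
    inf <- permutationInference(mapsFromMatrix(M, c(2, 2, 2)), des,
                                nPerm = 500, seed = 1),
    "exhaustively")
  expect_identical(inf@nPermutations, as.integer(factorial(5)))
  ## exhaustive p-values live on the grid k/120 and are >= 1/120
  expect_true(all(imgData(inf@fweP) >= 1 / 120, na.rm = TRUE))
})
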