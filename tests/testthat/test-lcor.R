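test_that("confound regression produces residuals orthogonal to regressors", {
  img <- noiseImage(c(3, 3, 3), nt = 40, seed = 5)
  nt <- 40

  ## intercept-only regression is temporal demeaning
  out <- regressConfounds(img, confoundSet())
  manual <- apply(imgData(img), 1:3, function(s) s - mean(s))
  expect_equal(as.vector(imgData(out)),
               as.vector(aperm(manual, c(2, 3, 4, 1))), tolerance = 1e-12)

  ## a voxel equal to a confound regresses to (numerically) zero
  set.seed(7)
  conf <- matrix(rnorm(nt), ncol = 1)
  img2 <- img
  img2@data[1, 1, 1, ] <- conf[, 1]
  out2 <- regressConfounds(img2, confoundSet(conf, "c1"))
  expect_lt(max(abs(imgData(out2)[1, 1, 1, ])), 1e-10)

  ## y = 2c + e matches the brute-force normal-equations residual
  e <- rnorm(nt)
  img3 <- img
  img3@data[2, 2, 2, ] <- 2 * conf[, 1] + e
  out3 <- regressConfounds(img3, confoundSet(conf, "c1"))
  X <- cbind(1, conf)
  oracle <- e - X %*% solve(t(X) %*% X, t(X) %*% e)
  expect_equal(as.vector(imgData(out3)[2, 2, 2, ]), as.vector(oracle),
               tolerance = 1e-10)

  ## residuals orthogonal to every regressor
  Y <- matrix(imgData(out3), ncol = nt)
  expect_lt(max(abs(Y %*% conf)) / max(abs(Y)), 1e-8)

  ## collinear columns are dropped with a warning
  expect_warning(
    regressConfounds(img, confoundSet(cbind(conf, 2 * conf), c("a", "b"))),
    "collinear")
})

test_that("LCOR equals its brute-force weighted-correlation oracle", {
  ## 3-voxel line with hand-chosen series: weighted mean of pairwise
  ## correlations with explicit Gaussian weights
  dat <- array(0, dim = c(3, 1, 1, 5))
  dat[1, 1, 1, ] <- c(1, 2, 3, 4, 5)
  dat[2, 1, 1, ] <- c(2, 1, 4, 3, 6)
  dat[3, 1, 1, ] <- c(5, 3, 4, 1, 2)
  img <- functionalImage(dat, voxelSizeMm = 2)
  p <- lcorParams(kernelFwhmMm = 4, smoothFwhmMm = 0,
                  truncationRadiusMm = 8)
  got <- imgData(computeLcor(img, p))
  sigma <- 4 / (2 * sqrt(2 * log(2)))
  w2 <- exp(-4 / (2 * sigma^2))   # 2 mm apart
  w4 <- exp(-16 / (2 * sigma^2))  # 4 mm apart
  r12 <- cor(dat[1, 1, 1, ], dat[2, 1, 1, ])
  r13 <- cor(dat[1, 1, 1, ], dat[3, 1, 1, ])
  r23 <- cor(dat[2, 1, 1, ], dat[3, 1, 1, ])
  expect_equal(got[1, 1, 1], (w2 * r12 + w4 * r13) / (w2 + w4),
               tolerance = 1e-12)
  expect_equal(got[2, 1, 1], (w2 * r12 + w2 * r23) / (2 * w2),
               tolerance = 1e-12)

  ## random image, random mask: oracle equivalence at 1e-10
  img2 <- noiseImage(c(5, 4, 4), nt = 12, seed = 11)
  set.seed(12)
  mask <- array(runif(80) < 0.7, dim = c(5, 4, 4))
  p2 <- lcorParams(kernelFwhmMm = 6, smoothFwhmMm = 0, mask = mask)
  got2 <- imgData(computeLcor(img2, p2))
  want2 <- lcorOracle(img2, p2)
  expect_equal(got2, want2, tolerance = 1e-10)
})

test_that("LCOR respects correlation structure and degenerate inputs", {
  ## identical series everywhere -> LCOR = 1
  base <- rnorm(20)
  dat <- array(rep(base, each = 27), dim = c(3, 3, 3, 20))
  img <- functionalImage(dat, voxelSizeMm = 3)
  out <- imgData(computeLcor(img, lcorParams(smoothFwhmMm = 0)))
  expect_equal(as.vector(out), rep(1, 27), tolerance = 1e-10)

  ## invariant to per-voxel affine rescaling of the series
  img2 <- noiseImage(c(4, 4, 4), nt = 25, seed = 3)
  set.seed(4)
  a <- runif(64, 0.5, 3); b <- rnorm(64)
  dat3 <- array(0, dim = c(4, 4, 4, 25))
  for (v in 1:64) {
    i <- arrayInd(v, c(4, 4, 4))
    dat3[i[1], i[2], i[3], ] <- a[v] * img2@data[i[1], i[2], i[3], ] + b[v]
  }
  p <- lcorParams(kernelFwhmMm = 8, smoothFwhmMm = 0)
  expect_equal(imgData(computeLcor(functionalImage(dat3, voxelSizeMm = 3), p)),
               imgData(computeLcor(img2, p)), tolerance = 1e-10)

  ## zero-variance voxel becomes missing, with a warning
  img4 <- noiseImage(c(3, 3, 1), nt = 15, seed = 8)
  img4@data[2, 2, 1, ] <- 5
  expect_warning(out4 <- computeLcor(img4, lcorParams(kernelFwhmMm = 8,
                                                      smoothFwhmMm = 0)),
                 "zero-variance")
  badIdx <- which(is.na(imgData(out4)))
  expect_identical(badIdx, 5L)   # linear index of voxel (2, 2, 1)

  ## fewer than 2 masked voxels errors
  m <- array(FALSE, dim = c(3, 3, 1)); m[1] <- TRUE
  expect_error(computeLcor(img4, lcorParams(mask = m)), "at least 2")
})

test_that("true LCOR rises monotonically with the synchronization weight", {
  ## one subject whose regions span w in [0.1, 0.9]; regional mean LCOR
  ## must track w almost perfectly at t = 200
  spec <- tinySpec(nTimepoints = 200L, seed = 21)
  atlas <- tinyAtlas(spec)
  R <- nrow(regionTable(atlas))
  w <- seq(0.1, 0.9, length.out = R)
  set.seed(22)
  vol <- neurocoloc:::subjectVolume(w, imgData(atlas), NULL, 200, 1)
  img <- functionalImage(vol, affine = imgAffine(atlas))
  lcor <- computeLcor(img, lcorParams(kernelFwhmMm = 6, smoothFwhmMm = 0,
                                      mask = imgData(atlas) > 0))
  rv <- regionValues(parcellate(lcor, atlas))
  expect_gt(cor(w, rv, method = "spearman"), 0.95)
})

test_that("gaussian smoothing is exact in its closed-form limits", {
  img <- noiseImage(c(5, 5, 5), nt = 2, seed = 9)
  map <- statMap(imgData(img)[, , , 1], voxelSizeMm = 2)

  ## fwhm = 0 is the identity
  expect_identical(imgData(gaussianSmooth(map, 0)), imgData(map))

  ## constant maps are preserved exactly (mask renormalization)
  cmap <- statMap(array(3.5, dim = c(5, 5, 5)), voxelSizeMm = 2)
  expect_equal(as.vector(imgData(gaussianSmooth(cmap, 5))),
               rep(3.5, 125), tolerance = 1e-12)

  ## delta at the centre reproduces the discrete separable kernel
  dmap <- statMap(array(0, dim = c(9, 9, 9)), voxelSizeMm = 1)
  dmap@data[5, 5, 5] <- 1
  fwhm <- 2  # voxels (1 mm voxels)
  sm <- imgData(gaussianSmooth(dmap, fwhm))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  rad <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- dnorm(-rad:rad, sd = sigma); k <- k / sum(k)
  ## interior voxels (kernel fully inside the grid): pure separable product
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    want <- k[dx + rad + 1] * k[dy + rad + 1] * k[dz + rad + 1]
    expect_equal(sm[5 + dx, 5 + dy, 5 + dz], want, tolerance = 1e-6)
  }
  ## near the edge the smoothed-mask renormalization divides by the
  ## in-bounds kernel mass per axis
  inb <- function(p) sum(k[pmax(1, p - rad):pmin(9, p + rad) - p + rad + 1])
  want <- k[3 + rad + 1] * k[rad + 1]^2 / (inb(8) * inb(5)^2)
  expect_equal(sm[5, 5, 8], want, tolerance = 1e-6)
})
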